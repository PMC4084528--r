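# Trajectory and energy output: standard XYZ, minimal PDB
# (CRYST1 + ATOM records), tab-separated energy logs, and the YAML
# machine/workload configuration reader.

#' Write a system snapshot in XYZ format
#'
#' Standard XYZ block: particle count, a comment line carrying the step
#' number and box, then one `element x y z` row per particle.
#'
#' @param system an [md_system()].
#' @param file path.
#' @param step step number written into the comment line.
#' @param elements per-particle element symbols (default `"X"` + type
#'   index).
#' @param append append to an existing trajectory.
#' @export
write_xyz <- function(system, file, step = 0L, elements = NULL,
                      append = FALSE) {
  stopifnot(inherits(system, "md_system"))
  if (is.null(elements)) elements <- paste0("X", system$type_idx)
  lines <- c(
    sprintf("%d", system$n),
    sprintf("step=%d box=%.6f %.6f %.6f", step,
            system$box[1], system$box[2], system$box[3]),
    sprintf("%-4s %14.8f %14.8f %14.8f", elements,
            system$positions[, 1], system$positions[, 2],
            system$positions[, 3])
  )
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Read the last frame of an XYZ file
#'
#' @param file path written by [write_xyz()].
#' @return list with `positions`, `elements`, `step`, `box`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  # find the last frame header
  n <- as.integer(lines[1])
  frame_len <- n + 2L
  n_frames <- length(lines) %/% frame_len
  start <- (n_frames - 1L) * frame_len + 1L
  comment <- lines[start + 1L]
  step <- as.integer(sub(".*step=(\\d+).*", "\\1", comment))
  box <- as.numeric(strsplit(sub(".*box=", "", comment), "\\s+")[[1]])
  rows <- strsplit(trimws(lines[(start + 2L):(start + 1L + n)]), "\\s+")
  elements <- vapply(rows, `[`, character(1), 1)
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  list(positions = pos, elements = elements, step = step, box = box)
}

#' Write a minimal PDB snapshot
#'
#' CRYST1 record with the box, then fixed-column ATOM records and END.
#'
#' @param system an [md_system()].
#' @param file path.
#' @param elements per-particle element symbols (at most 2 characters
#'   used).
#' @export
write_pdb <- function(system, file, elements = NULL) {
  stopifnot(inherits(system, "md_system"))
  if (is.null(elements)) elements <- rep("C", system$n)
  el <- toupper(substr(elements, 1, 2))
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            system$box[1], system$box[2], system$box[3], 90, 90, 90),
    sprintf(
      "ATOM  %5d %-4s MOL A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(system$n) %% 100000L, substr(el, 1, 4), 1L,
      system$positions[, 1], system$positions[, 2], system$positions[, 3],
      1, 0, el
    ),
    "END"
  )
  writeLines(lines, file)
  invisible(file)
}

#' Write an energy record as tab-separated text
#'
#' @param energies data frame from [run_md()].
#' @param file path or connection.
#' @export
write_energies <- function(energies, file) {
  utils::write.table(energies, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a machine/workload configuration
#'
#' YAML configuration with optional `machine`, `workload`, `link` and
#' `latency` sections whose keys override the corresponding constructor
#' defaults.
#'
#' @param file YAML path.
#' @return list with `machine` ([machine_spec()]) and `workload`
#'   ([workload_spec()]).
#' @export
read_machine_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  link <- do.call(link_spec, as.list(cfg$link %||% list()))
  latency <- do.call(latency_model, as.list(cfg$latency %||% list()))
  margs <- as.list(cfg$machine %||% list())
  margs$link <- link
  margs$latency <- latency
  machine <- do.call(machine_spec, margs)
  workload <- do.call(workload_spec, as.list(cfg$workload %||% list()))
  list(machine = machine, workload = workload)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
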