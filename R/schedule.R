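# Per-timestep task schedule: the dependency graph a chip follows in one
# MD step -- particle distribution first, then charge assignment /
# non-bonded / bonded work, the Poisson solve and back interpolation on
# the long-range branch, force gathering, and the coordinate update last.

#' Per-step task schedule
#'
#' @param deps named list mapping each task to its prerequisite tasks.
#'   The default encodes: distribute -> (charge_assign, nonbonded, bonded);
#'   charge_assign -> poisson -> back_interp; (nonbonded, bonded,
#'   back_interp) -> gather -> update.
#' @return an object of class `step_schedule` with a validated topological
#'   order.
#' @export
step_schedule <- function(deps = list(
  distribute = character(0),
  charge_assign = "distribute",
  nonbonded = "distribute",
  bonded = "distribute",
  poisson = "charge_assign",
  back_interp = "poisson",
  gather = c("nonbonded", "bonded", "back_interp"),
  update = "gather"
)) {
  tasks <- names(deps)
  if (any(!unlist(deps) %in% tasks)) stop("dependency on an unknown task")
  order <- character(0)
  remaining <- deps
  while (length(remaining) > 0L) {
    ready <- names(remaining)[vapply(remaining, function(d) {
      all(d %in% order)
    }, logical(1))]
    if (length(ready) == 0L) stop("cyclic schedule")
    order <- c(order, ready)
    remaining <- remaining[setdiff(names(remaining), ready)]
  }
  if (order[1] != "distribute" && "distribute" %in% tasks) {
    stop("distribute must be first")
  }
  if (utils::tail(order, 1) != "update" && "update" %in% tasks) {
    stop("update must be last")
  }
  structure(list(deps = deps, order = order), class = "step_schedule")
}

#' @export
print.step_schedule <- function(x, ...) {
  cat("<step_schedule>", paste(x$order, collapse = " -> "), "\n")
  invisible(x)
}

# longest path through the schedule given per-task times; tasks on
# independent branches overlap
schedule_critical_path <- function(schedule, task_times) {
  stopifnot(inherits(schedule, "step_schedule"))
  finish <- stats::setNames(numeric(length(schedule$order)), schedule$order)
  for (task in schedule$order) {
    pre <- schedule$deps[[task]]
    start <- if (length(pre) == 0L) 0 else max(finish[pre])
    tt <- if (task %in% names(task_times)) task_times[[task]] else 0
    finish[task] <- start + tt
  }
  max(finish)
}
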