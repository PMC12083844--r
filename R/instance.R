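#' @keywords internal
"_PACKAGE"

# Severity classes are always stored in this order: column/dimension order of
# every casualty and capacity table in the package.
SEVERITIES <- c("serious", "moderate")

#' Severity class parameters
#'
#' A severity class bundles the two scalars that drive the objective for one
#' triage category: the urgency weight multiplying its accrued trauma score,
#' and the per-hour deterioration rate of untreated casualties of that class.
#'
#' @param label Either `"serious"` or `"moderate"`.
#' @param urgency_weight Positive dimensionless weight (2 for serious and 1
#'   for moderate in the embedded case study).
#' @param base_deterioration Per-hour deterioration rate in `(0, 1]`
#'   (0.8 serious, 0.2 moderate in the embedded case study).
#' @return An object of class `severity_class`.
#' @export
severity_class <- function(label, urgency_weight, base_deterioration) {
  label <- match.arg(label, SEVERITIES)
  stopifnot(is.numeric(urgency_weight), length(urgency_weight) == 1L,
            is.numeric(base_deterioration), length(base_deterioration) == 1L)
  if (urgency_weight <= 0)
    stop("urgency_weight must be > 0", call. = FALSE)
  if (base_deterioration <= 0 || base_deterioration > 1)
    stop("base_deterioration must lie in (0, 1]", call. = FALSE)
  structure(list(label = label,
                 urgency_weight = as.numeric(urgency_weight),
                 base_deterioration = as.numeric(base_deterioration)),
            class = "severity_class")
}

#' Fleet specification
#'
#' @param vehicles Number of road rescue vehicles available.
#' @param helicopters Number of helicopters available.
#' @param vehicle_capacity Casualties carried per vehicle trip.
#' @param helicopter_capacity Casualties carried per helicopter trip.
#' @return A list of class `fleet_spec`.
#' @export
fleet_spec <- function(vehicles, helicopters,
                       vehicle_capacity = 6L, helicopter_capacity = 12L) {
  x <- list(vehicles = as.integer(vehicles),
            helicopters = as.integer(helicopters),
            vehicle_capacity = as.integer(vehicle_capacity),
            helicopter_capacity = as.integer(helicopter_capacity))
  if (any(vapply(x, function(v) is.na(v) || v < 1L, logical(1))))
    stop("all fleet fields must be integers >= 1", call. = FALSE)
  structure(x, class = "fleet_spec")
}

#' Assemble a problem instance
#'
#' An instance is the full datum of one rescue planning problem: index sets,
#' nominal casualty counts, travel times, hospital capacities, fleet, and the
#' severity parameters.  Temporary hospitals share one severity-aggregated
#' capacity (stored per hospital to allow capacity sweeps); general hospitals
#' have per-severity capacities.
#'
#' @param areas,temp_hospitals,general_hospitals Character vectors of ids
#'   (e.g. `"I1"`, `"J3"`, `"K2"`).  The three sets must be disjoint.
#' @param casualties Integer matrix of nominal counts, rows = areas, columns
#'   = `c("serious", "moderate")`.
#' @param road_times Numeric matrix of travel hours, areas x temporary
#'   hospitals, all entries positive.
#' @param air_times Numeric matrix of travel hours, temporary x general
#'   hospitals, all entries positive.
#' @param fleet A [fleet_spec()].
#' @param temp_capacity Either a single capacity shared by all temporary
#'   hospitals or a named vector over `temp_hospitals` (head-count, both
#'   severities pooled).
#' @param general_capacity Integer matrix, general hospitals x severities.
#' @param severities List with elements `serious` and `moderate`, each a
#'   [severity_class()].
#' @param post_treatment_factor Fraction in `(0, 1]` to which the
#'   deterioration rate drops after field treatment (default 0.2).
#' @return An object of class `evac_instance`.
#' @export
evac_instance <- function(areas, temp_hospitals, general_hospitals,
                          casualties, road_times, air_times, fleet,
                          temp_capacity, general_capacity,
                          severities = default_severities(),
                          post_treatment_factor = 0.2) {
  areas <- as.character(areas)
  temp_hospitals <- as.character(temp_hospitals)
  general_hospitals <- as.character(general_hospitals)
  casualties <- as.matrix(casualties)
  storage.mode(casualties) <- "double"
  rownames(casualties) <- rownames(casualties) %||% areas
  colnames(casualties) <- colnames(casualties) %||% SEVERITIES
  casualties <- casualties[areas, SEVERITIES, drop = FALSE]
  road_times <- as.matrix(road_times)
  rownames(road_times) <- rownames(road_times) %||% areas
  colnames(road_times) <- colnames(road_times) %||% temp_hospitals
  air_times <- as.matrix(air_times)
  rownames(air_times) <- rownames(air_times) %||% temp_hospitals
  colnames(air_times) <- colnames(air_times) %||% general_hospitals
  if (length(temp_capacity) == 1L && is.null(names(temp_capacity)))
    temp_capacity <- stats::setNames(rep(as.numeric(temp_capacity),
                                         length(temp_hospitals)),
                                     temp_hospitals)
  general_capacity <- as.matrix(general_capacity)
  rownames(general_capacity) <- rownames(general_capacity) %||% general_hospitals
  colnames(general_capacity) <- colnames(general_capacity) %||% SEVERITIES
  inst <- structure(list(
    areas = areas,
    temp_hospitals = temp_hospitals,
    general_hospitals = general_hospitals,
    casualties = casualties,
    road_times = road_times,
    air_times = air_times,
    fleet = fleet,
    capacities = list(temp = temp_capacity,
                      general = general_capacity[general_hospitals,
                                                 SEVERITIES, drop = FALSE]),
    severities = severities,
    post_treatment_factor = as.numeric(post_treatment_factor)
  ), class = "evac_instance")
  rep <- validate_instance(inst)
  if (length(rep$errors))
    stop("invalid instance:\n", format_report_items(rep$errors), call. = FALSE)
  inst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default severity parameterisation
#'
#' Urgency weights 2/1 and deterioration rates 0.8/0.2 per hour for the
#' serious and moderate classes.
#' @return List with `serious` and `moderate` [severity_class()] objects.
#' @export
default_severities <- function() {
  list(serious = severity_class("serious", 2, 0.8),
       moderate = severity_class("moderate", 1, 0.2))
}

#' Validate an instance
#'
#' Checks every structural invariant (complete positive travel-time matrices,
#' non-negative integral casualty counts, positive capacities, disjoint index
#' sets, severity ordering) and returns a report rather than throwing.  A
#' warning -- not an error -- is recorded when the pooled temporary-hospital
#' capacity cannot hold the nominal casualty total, since robust planning may
#' legitimately need more capacity than is available.
#'
#' @param inst An `evac_instance` (or a list shaped like one).
#' @return A `validation_report` with `errors` and `warnings`, each a list of
#'   `(code, message)` pairs.
#' @export
validate_instance <- function(inst) {
  errors <- list(); warnings <- list()
  err <- function(code, msg) errors[[length(errors) + 1L]] <<- list(code = code, message = msg)
  wrn <- function(code, msg) warnings[[length(warnings) + 1L]] <<- list(code = code, message = msg)

  if (!length(inst$areas)) err("empty_set", "area list is empty")
  if (!length(inst$temp_hospitals)) err("empty_set", "temporary hospital list is empty")
  if (!length(inst$general_hospitals)) err("empty_set", "general hospital list is empty")
  ids <- c(inst$areas, inst$temp_hospitals, inst$general_hospitals)
  if (anyDuplicated(ids))
    err("overlapping_sets", "area/hospital ids must be pairwise distinct")

  q <- inst$casualties
  if (!identical(dim(q), c(length(inst$areas), 2L)) ||
      !identical(colnames(q), SEVERITIES) ||
      !setequal(rownames(q), inst$areas)) {
    err("casualties_shape", "casualty table must cover every (area, severity) pair")
  } else {
    if (anyNA(q) || any(q < 0)) err("negative_casualties", "casualty counts must be >= 0")
    else if (any(q != round(q))) err("fractional_casualties", "casualty counts must be integral")
  }

  check_times <- function(m, rows, cols, what) {
    if (!identical(dim(m), c(length(rows), length(cols))) ||
        !setequal(rownames(m), rows) || !setequal(colnames(m), cols))
      err("times_shape", sprintf("%s travel-time matrix is incomplete", what))
    else if (anyNA(m) || any(m <= 0))
      err("nonpositive_times", sprintf("%s travel times must all be > 0", what))
  }
  check_times(inst$road_times, inst$areas, inst$temp_hospitals, "road")
  check_times(inst$air_times, inst$temp_hospitals, inst$general_hospitals, "air")

  fl <- inst$fleet
  if (!all(c("vehicles", "helicopters", "vehicle_capacity",
             "helicopter_capacity") %in% names(fl)) ||
      any(unlist(fl[c("vehicles", "helicopters", "vehicle_capacity",
                      "helicopter_capacity")]) < 1))
    err("fleet", "fleet fields must all be >= 1")

  cp <- inst$capacities
  if (!setequal(names(cp$temp), inst$temp_hospitals) || any(cp$temp < 0))
    err("temp_capacity", "temporary capacities must be >= 0 and cover every hospital")
  if (!setequal(rownames(cp$general), inst$general_hospitals) ||
      !identical(colnames(cp$general), SEVERITIES) || any(cp$general < 0))
    err("general_capacity", "general capacities must be >= 0 per (hospital, severity)")

  sv <- inst$severities
  if (!all(c("serious", "moderate") %in% names(sv))) {
    err("severities", "both severity classes must be present")
  } else {
    if (sv$serious$urgency_weight < sv$moderate$urgency_weight)
      err("severity_order", "serious urgency weight must be >= moderate")
    if (sv$serious$base_deterioration < sv$moderate$base_deterioration)
      err("severity_order", "serious deterioration rate must be >= moderate")
  }
  f <- inst$post_treatment_factor
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    err("post_treatment_factor", "post-treatment factor must lie in (0, 1]")

  if (!length(errors)) {
    total <- sum(inst$casualties)
    pool <- sum(inst$capacities$temp)
    if (pool < total)
      wrn("temp_capacity_short",
          sprintf("pooled temporary capacity %g < %g nominal casualties; instance is likely infeasible",
                  pool, total))
    for (s in SEVERITIES)
      if (sum(inst$capacities$general[, s]) < sum(inst$casualties[, s]))
        wrn("general_capacity_short",
            sprintf("pooled general capacity for %s casualties is below the nominal total", s))
  }
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

format_report_items <- function(items) {
  paste(vapply(items, function(x) sprintf("  [%s] %s", x$code, x$message),
               character(1)), collapse = "\n")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  if (length(x$errors)) cat("errors:\n", format_report_items(x$errors), "\n", sep = "")
  if (length(x$warnings)) cat("warnings:\n", format_report_items(x$warnings), "\n", sep = "")
  invisible(x)
}

#' @export
print.evac_instance <- function(x, ...) {
  cat(sprintf("evacuation instance: %d areas, %d temporary, %d general hospitals\n",
              length(x$areas), length(x$temp_hospitals), length(x$general_hospitals)))
  cat(sprintf("  casualties: %d serious + %d moderate = %d total\n",
              sum(x$casualties[, "serious"]), sum(x$casualties[, "moderate"]),
              sum(x$casualties)))
  cat(sprintf("  fleet: %d vehicles (cap %d), %d helicopters (cap %d)\n",
              x$fleet$vehicles, x$fleet$vehicle_capacity,
              x$fleet$helicopters, x$fleet$helicopter_capacity))
  invisible(x)
}

#' Total nominal casualties of an instance
#'
#' @param inst An `evac_instance`.
#' @param severity Optional severity label to restrict the total.
#' @return Numeric count.
#' @export
total_casualties <- function(inst, severity = NULL) {
  if (is.null(severity)) sum(inst$casualties)
  else sum(inst$casualties[, match.arg(severity, SEVERITIES)])
}
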