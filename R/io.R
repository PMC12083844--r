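# Instance serialization: a versioned JSON document, or a CSV bundle with
# one file per table (casualties, road times, air times, fleet, capacities,
# scalar parameters).

INSTANCE_SCHEMA_VERSION <- "1.0"

#' Write an instance to disk
#'
#' @param inst An [evac_instance()].
#' @param path Output path.  For `format = "json"` a file; for
#'   `format = "csv"` a directory (created if missing) receiving one CSV per
#'   table.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_instance <- function(inst, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      schema_version = INSTANCE_SCHEMA_VERSION,
      areas = inst$areas,
      temp_hospitals = inst$temp_hospitals,
      general_hospitals = inst$general_hospitals,
      casualties = casualty_records(inst$casualties),
      road_times = matrix_to_nested(inst$road_times),
      air_times = matrix_to_nested(inst$air_times),
      fleet = unclass(inst$fleet),
      capacities = list(temp = as.list(inst$capacities$temp),
                        general = matrix_to_nested(inst$capacities$general)),
      severity_params = lapply(inst$severities, unclass),
      post_treatment_factor = inst$post_treatment_factor)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    w <- function(d, f) utils::write.csv(d, file.path(path, f), row.names = FALSE)
    w(data.frame(area = rep(rownames(inst$casualties), 2),
                 severity = rep(SEVERITIES, each = nrow(inst$casualties)),
                 count = c(inst$casualties[, 1], inst$casualties[, 2])),
      "casualties.csv")
    w(cbind(data.frame(id = rownames(inst$road_times)),
            as.data.frame(inst$road_times)), "road_times.csv")
    w(cbind(data.frame(id = rownames(inst$air_times)),
            as.data.frame(inst$air_times)), "air_times.csv")
    w(data.frame(field = names(unclass(inst$fleet)),
                 value = unlist(inst$fleet)), "fleet.csv")
    w(data.frame(id = names(inst$capacities$temp),
                 capacity = as.numeric(inst$capacities$temp)),
      "temp_capacity.csv")
    w(cbind(data.frame(id = rownames(inst$capacities$general)),
            as.data.frame(inst$capacities$general)), "general_capacity.csv")
    sv <- inst$severities
    w(data.frame(label = SEVERITIES,
                 urgency_weight = c(sv$serious$urgency_weight,
                                    sv$moderate$urgency_weight),
                 base_deterioration = c(sv$serious$base_deterioration,
                                        sv$moderate$base_deterioration)),
      "severity_params.csv")
    w(data.frame(field = "post_treatment_factor",
                 value = inst$post_treatment_factor), "parameters.csv")
  }
  invisible(path)
}

casualty_records <- function(m) {
  recs <- list()
  for (a in rownames(m)) for (s in colnames(m))
    recs[[length(recs) + 1L]] <- list(area = a, severity = s,
                                      count = as.numeric(m[a, s]))
  recs
}

matrix_to_nested <- function(m) {
  out <- list()
  for (r in rownames(m)) out[[r]] <- as.list(stats::setNames(m[r, ], colnames(m)))
  out
}

nested_to_matrix <- function(x, rows, cols, what) {
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (r in rows) {
    row <- x[[r]]
    if (is.null(row)) stop(sprintf("%s: missing row '%s'", what, r), call. = FALSE)
    for (cc in cols) {
      v <- row[[cc]]
      if (is.null(v)) stop(sprintf("%s: missing cell (%s, %s)", what, r, cc),
                           call. = FALSE)
      m[r, cc] <- as.numeric(v)
    }
  }
  m
}

#' Load an instance from disk
#'
#' Reads an instance written by [write_instance()] (JSON document or CSV
#' bundle directory).  Field-level problems raise errors naming the
#' offending field; invariant violations are rejected through
#' [validate_instance()].
#'
#' @param path File (JSON) or directory (CSV bundle).
#' @param format `"json"` or `"csv"`; guessed from `path` when missing.
#' @return An [evac_instance()].
#' @export
load_instance <- function(path, format = NULL) {
  if (is.null(format)) format <- if (dir.exists(path)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (format == "json") load_instance_json(path) else load_instance_csv(path)
}

load_instance_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("areas", "temp_hospitals", "general_hospitals", "casualties",
            "road_times", "air_times", "fleet", "capacities",
            "severity_params", "post_treatment_factor")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("instance document lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  areas <- unlist(doc$areas); temps <- unlist(doc$temp_hospitals)
  gens <- unlist(doc$general_hospitals)
  q <- matrix(NA_real_, length(areas), 2, dimnames = list(areas, SEVERITIES))
  for (rec in doc$casualties) {
    if (is.null(rec$area) || is.null(rec$severity) || is.null(rec$count))
      stop("casualties: each record needs area, severity, count", call. = FALSE)
    q[rec$area, rec$severity] <- as.numeric(rec$count)
  }
  if (anyNA(q)) stop("casualties: table does not cover every (area, severity) pair",
                     call. = FALSE)
  fl <- doc$fleet
  sv <- doc$severity_params
  evac_instance(
    areas = areas, temp_hospitals = temps, general_hospitals = gens,
    casualties = q,
    road_times = nested_to_matrix(doc$road_times, areas, temps, "road_times"),
    air_times = nested_to_matrix(doc$air_times, temps, gens, "air_times"),
    fleet = fleet_spec(fl$vehicles, fl$helicopters,
                       fl$vehicle_capacity, fl$helicopter_capacity),
    temp_capacity = unlist(doc$capacities$temp)[temps],
    general_capacity = nested_to_matrix(doc$capacities$general, gens,
                                        SEVERITIES, "capacities$general"),
    severities = list(
      serious = severity_class("serious", sv$serious$urgency_weight,
                               sv$serious$base_deterioration),
      moderate = severity_class("moderate", sv$moderate$urgency_weight,
                                sv$moderate$base_deterioration)),
    post_treatment_factor = as.numeric(doc$post_treatment_factor))
}

load_instance_csv <- function(path) {
  rd <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("CSV bundle lacks ", f, call. = FALSE)
    utils::read.csv(fp, check.names = FALSE)
  }
  cas <- rd("casualties.csv")
  areas <- unique(cas$area)
  q <- matrix(NA_real_, length(areas), 2, dimnames = list(areas, SEVERITIES))
  for (i in seq_len(nrow(cas))) q[cas$area[i], cas$severity[i]] <- cas$count[i]
  road <- rd("road_times.csv"); rownames(road) <- road$id; road$id <- NULL
  air <- rd("air_times.csv"); rownames(air) <- air$id; air$id <- NULL
  fl <- rd("fleet.csv"); flv <- stats::setNames(fl$value, fl$field)
  tc <- rd("temp_capacity.csv")
  gc <- rd("general_capacity.csv"); rownames(gc) <- gc$id; gc$id <- NULL
  sp <- rd("severity_params.csv")
  pr <- rd("parameters.csv")
  evac_instance(
    areas = areas, temp_hospitals = colnames(road),
    general_hospitals = colnames(air),
    casualties = q, road_times = as.matrix(road), air_times = as.matrix(air),
    fleet = fleet_spec(flv[["vehicles"]], flv[["helicopters"]],
                       flv[["vehicle_capacity"]], flv[["helicopter_capacity"]]),
    temp_capacity = stats::setNames(tc$capacity, tc$id),
    general_capacity = as.matrix(gc),
    severities = list(
      serious = severity_class("serious",
                               sp$urgency_weight[sp$label == "serious"],
                               sp$base_deterioration[sp$label == "serious"]),
      moderate = severity_class("moderate",
                                sp$urgency_weight[sp$label == "moderate"],
                                sp$base_deterioration[sp$label == "moderate"])),
    post_treatment_factor = pr$value[pr$field == "post_treatment_factor"])
}
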