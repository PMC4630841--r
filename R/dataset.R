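#' Landmark datasets
#'
#' A `landmark_dataset` bundles a landmark template with per-specimen 3D
#' coordinates (in mm, as digitized), a missing-landmark mask and specimen
#' metadata. Coordinates are stored as a `k x 3 x n` array; the missing mask
#' is a `k x n` logical matrix (`TRUE` = landmark not recorded); metadata is a
#' data frame with one row per specimen.
#'
#' @param template A [load_template()] object.
#' @param coords Numeric `k x 3 x n` array (or `k x 3` matrix for n = 1).
#' @param meta Data frame with columns `specimen_id`, `species`, `age_class`
#'   (`"juvenile"`/`"adult"`), `structure`; optional `idas_stage` (integer
#'   1-5) and `site`.
#' @param missing Optional `k x n` logical matrix; defaults to marking
#'   non-finite coordinates as missing.
#' @param provenance Character vector of free-text processing log lines.
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(template, coords, meta, missing = NULL,
                             provenance = character()) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (is.null(missing)) {
    missing <- matrix(FALSE, k, n)
    for (i in seq_len(n)) missing[, i] <- !apply(is.finite(coords[, , i]), 1L, all)
  }
  if (is.null(meta$idas_stage)) meta$idas_stage <- rep(NA_integer_, nrow(meta))
  if (is.null(meta$site)) meta$site <- rep(NA_character_, nrow(meta))
  ds <- structure(
    list(template = template, coords = coords, missing = missing,
         meta = meta, provenance = provenance),
    class = "landmark_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a landmark dataset
#'
#' Checks template/coordinate agreement, finiteness of observed coordinates,
#' and consistency of the age class with the dental age stage when both are
#' present (stages 1-2 are juvenile, 3-5 adult).
#'
#' @param ds A [landmark_dataset()].
#' @return The dataset, invisibly; errors describe the offending specimen.
#' @export
validate_dataset <- function(ds) {
  k <- length(ds$template$landmark_names)
  if (dim(ds$coords)[1L] != k)
    stop("dataset invalid: ", dim(ds$coords)[1L], " landmarks per specimen, ",
         "template '", ds$template$structure_name, "' expects ", k, call. = FALSE)
  if (dim(ds$coords)[2L] != 3L)
    stop("dataset invalid: coordinates must be 3D", call. = FALSE)
  n <- dim(ds$coords)[3L]
  if (nrow(ds$meta) != n)
    stop("dataset invalid: ", n, " specimens but ", nrow(ds$meta),
         " metadata rows", call. = FALSE)
  for (i in seq_len(n)) {
    obs <- !ds$missing[, i]
    if (any(obs) && !all(is.finite(ds$coords[obs, , i])))
      stop("dataset invalid: non-finite observed coordinates in specimen ",
           ds$meta$specimen_id[i], call. = FALSE)
    st <- ds$meta$idas_stage[i]
    if (!is.na(st)) {
      expect <- if (st <= 2L) "juvenile" else "adult"
      if (!is.na(ds$meta$age_class[i]) && ds$meta$age_class[i] != expect)
        stop("dataset invalid: specimen ", ds$meta$specimen_id[i],
             " has IDAS stage ", st, " but age class '",
             ds$meta$age_class[i], "'", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  n <- dim(x$coords)[3L]
  cat("Landmark dataset: ", n, " specimens x ", dim(x$coords)[1L],
      " landmarks (", x$template$structure_name, ")\n", sep = "")
  if (n) {
    tab <- table(x$meta$species, x$meta$age_class)
    print(tab)
  }
  miss <- sum(x$missing)
  if (miss) cat(miss, "missing landmark(s) across",
                sum(colSums(x$missing) > 0), "specimen(s)\n")
  invisible(x)
}

#' Number of specimens in a dataset
#' @param ds A [landmark_dataset()].
#' @return Integer count.
#' @export
n_specimens <- function(ds) dim(ds$coords)[3L]

#' Subset a landmark dataset by specimen
#' @param ds A [landmark_dataset()].
#' @param idx Integer or logical specimen index.
#' @return A [landmark_dataset()] with the selected specimens.
#' @export
subset_specimens <- function(ds, idx) {
  if (is.logical(idx)) idx <- which(idx)
  landmark_dataset(ds$template,
                   ds$coords[, , idx, drop = FALSE],
                   ds$meta[idx, , drop = FALSE],
                   missing = ds$missing[, idx, drop = FALSE],
                   provenance = ds$provenance)
}
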