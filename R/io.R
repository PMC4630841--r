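#' Read landmark files
#'
#' Reads 3D landmark data in either a TPS dialect or a flat CSV dialect into a
#' [landmark_dataset()].
#'
#' The TPS dialect uses `LM=k` blocks of `k` whitespace-separated `x y z` rows
#' followed by `KEY=VALUE` metadata lines (`SPECIES=`, `AGECLASS=`,
#' `STRUCTURE=`, optional `IDAS=`, `SITE=`, `SCALE=`) and a closing `ID=` line.
#' A coordinate triple of `9999` marks an unrecorded landmark (the value is
#' never used numerically: it becomes a missing-mask entry on read).
#'
#' The CSV dialect has columns `specimen_id, species, age_class, structure,
#' idas_stage, site, x1, y1, z1, ..., xk, yk, zk` with empty cells for missing
#' coordinates. Landmark numbering in both file formats is 1-based.
#'
#' @param path File path.
#' @param format `"tps"` or `"csv"`.
#' @param template A [load_template()] object the file must conform to.
#' @return A [landmark_dataset()].
#' @export
read_landmarks <- function(path, format = c("tps", "csv"), template) {
  format <- match.arg(format)
  if (format == "tps") read_landmarks_tps(path, template)
  else read_landmarks_csv(path, template)
}

MISSING_SENTINEL <- 9999

read_landmarks_tps <- function(path, template) {
  lines <- readLines(path)
  k <- length(template$landmark_names)
  coords <- list(); metas <- list(); missing <- list()
  i <- 1L; n_lines <- length(lines)
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM=", ln))
      stop("TPS parse error at line ", i, ": expected LM= block start, got '",
           ln, "'", call. = FALSE)
    klm <- suppressWarnings(as.integer(sub("^LM=", "", ln)))
    if (is.na(klm))
      stop("TPS parse error at line ", i, ": unreadable landmark count",
           call. = FALSE)
    if (klm != k)
      stop("TPS validation error at line ", i, ": LM=", klm,
           " does not match template '", template$structure_name,
           "' with ", k, " landmarks", call. = FALSE)
    if (i + klm > n_lines)
      stop("TPS parse error: truncated coordinate block starting line ", i,
           call. = FALSE)
    block <- matrix(NA_real_, klm, 3L)
    for (j in seq_len(klm)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]),
                                                   "\\s+")[[1]]))
      if (length(vals) != 3L || anyNA(vals))
        stop("TPS parse error at line ", i + j, " (landmark ", j,
             "): expected three numeric coordinates", call. = FALSE)
      block[j, ] <- vals
    }
    i <- i + klm + 1L
    meta <- list(specimen_id = NA_character_, species = NA_character_,
                 age_class = NA_character_,
                 structure = template$structure_name,
                 idas_stage = NA_integer_, site = NA_character_)
    scale <- 1
    while (i <= n_lines && trimws(lines[i]) != "" &&
           !grepl("^LM=", trimws(lines[i]))) {
      kv <- trimws(lines[i])
      if (!grepl("=", kv, fixed = TRUE))
        stop("TPS parse error at line ", i, ": expected KEY=VALUE, got '",
             kv, "'", call. = FALSE)
      key <- sub("=.*$", "", kv); val <- sub("^[^=]*=", "", kv)
      switch(key,
        ID = { meta$specimen_id <- val },
        SPECIES = { meta$species <- val },
        AGECLASS = { meta$age_class <- val },
        STRUCTURE = { meta$structure <- val },
        IDAS = { meta$idas_stage <- as.integer(val) },
        SITE = { meta$site <- val },
        SCALE = { scale <- as.numeric(val) },
        NULL  # unknown keys are ignored
      )
      i <- i + 1L
      if (key == "ID") break  # ID= closes a specimen block
    }
    miss <- apply(block == MISSING_SENTINEL, 1L, all)
    block <- block * scale
    block[miss, ] <- NA_real_
    coords[[length(coords) + 1L]] <- block
    missing[[length(missing) + 1L]] <- miss
    metas[[length(metas) + 1L]] <- meta
  }
  assemble_dataset(template, coords, missing, metas,
                   paste0("read ", length(coords), " specimen(s) from TPS ", path))
}

read_landmarks_csv <- function(path, template) {
  k <- length(template$landmark_names)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("specimen_id", "species", "age_class", "structure")
  if (!all(need %in% names(df)))
    stop("CSV parse error: missing metadata columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  coord_cols <- paste0(rep(c("x", "y", "z"), times = k),
                       rep(seq_len(k), each = 3L))
  if (!all(coord_cols %in% names(df)))
    stop("CSV validation error: expected coordinate columns x1..z", k,
         " for template '", template$structure_name, "'", call. = FALSE)
  coords <- list(); missing <- list(); metas <- list()
  for (i in seq_len(nrow(df))) {
    raw <- as.character(df[i, coord_cols])
    vals <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & is.na(vals)
    if (any(bad))
      stop("CSV parse error: non-numeric coordinate for specimen ",
           df$specimen_id[i], " (row ", i, ")", call. = FALSE)
    block <- matrix(vals, k, 3L, byrow = TRUE)
    miss <- apply(is.na(block) | block == MISSING_SENTINEL, 1L, any)
    block[miss, ] <- NA_real_
    coords[[i]] <- block
    missing[[i]] <- miss
    metas[[i]] <- list(
      specimen_id = df$specimen_id[i], species = df$species[i],
      age_class = df$age_class[i], structure = df$structure[i],
      idas_stage = if ("idas_stage" %in% names(df))
        suppressWarnings(as.integer(df$idas_stage[i])) else NA_integer_,
      site = if ("site" %in% names(df)) df$site[i] else NA_character_)
  }
  assemble_dataset(template, coords, missing, metas,
                   paste0("read ", nrow(df), " specimen(s) from CSV ", path))
}

assemble_dataset <- function(template, coords, missing, metas, log_line) {
  k <- length(template$landmark_names)
  n <- length(coords)
  arr <- array(NA_real_, dim = c(k, 3L, n))
  mm <- matrix(FALSE, k, n)
  for (i in seq_len(n)) { arr[, , i] <- coords[[i]]; mm[, i] <- missing[[i]] }
  meta <- do.call(rbind, lapply(metas, function(m)
    data.frame(m, stringsAsFactors = FALSE)))
  if (is.null(meta))
    meta <- data.frame(specimen_id = character(), species = character(),
                       age_class = character(), structure = character(),
                       idas_stage = integer(), site = character(),
                       stringsAsFactors = FALSE)
  landmark_dataset(template, arr, meta, missing = mm, provenance = log_line)
}

#' Write landmark files
#'
#' Writes a [landmark_dataset()] in the TPS or CSV dialect read by
#' [read_landmarks()]. Coordinates are written with 6 decimals, so a
#' write/read round trip reproduces coordinates to 1e-6 and all metadata
#' exactly. Missing landmarks are written as the `9999` sentinel triple (TPS)
#' or empty cells (CSV).
#'
#' @param ds A [landmark_dataset()].
#' @param path Output file path.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(ds, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  k <- length(ds$template$landmark_names)
  n <- n_specimens(ds)
  if (format == "tps") {
    out <- character(0)
    for (i in seq_len(n)) {
      block <- ds$coords[, , i]
      block[ds$missing[, i], ] <- MISSING_SENTINEL
      rows <- apply(block, 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
      m <- ds$meta[i, ]
      kv <- c(
        if (!is.na(m$species)) paste0("SPECIES=", m$species),
        if (!is.na(m$age_class)) paste0("AGECLASS=", m$age_class),
        if (!is.na(m$structure)) paste0("STRUCTURE=", m$structure),
        if (!is.na(m$idas_stage)) paste0("IDAS=", m$idas_stage),
        if (!is.na(m$site)) paste0("SITE=", m$site),
        paste0("ID=", m$specimen_id))
      out <- c(out, paste0("LM=", k), rows, kv)
    }
    writeLines(out, path)
  } else {
    coord_names <- paste0(rep(c("x", "y", "z"), times = k),
                          rep(seq_len(k), each = 3L))
    rows <- vapply(seq_len(n), function(i) {
      block <- ds$coords[, , i]
      vals <- sprintf("%.6f", flatten_config(block))
      vals[rep(ds$missing[, i], each = 3L)] <- ""
      m <- ds$meta[i, ]
      paste(c(m$specimen_id, m$species, m$age_class, m$structure,
              ifelse(is.na(m$idas_stage), "", m$idas_stage),
              ifelse(is.na(m$site), "", m$site), vals), collapse = ",")
    }, character(1))
    header <- paste(c("specimen_id", "species", "age_class", "structure",
                      "idas_stage", "site", coord_names), collapse = ",")
    writeLines(c(header, rows), path)
  }
  invisible(path)
}
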