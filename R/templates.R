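#' Landmark templates
#'
#' A landmark template records, for a skeletal structure, the ordered landmark
#' names, the bilateral left/right pairing and the midline (midsagittal)
#' membership needed for object-symmetry analysis. Two templates are packaged:
#'
#' * `"cranium36"` — 36 cranial landmarks covering both lateral sides:
#'   14 bilateral pairs plus 8 unpaired midline landmarks.
#' * `"mandible9"` — 9 landmarks digitized on one hemimandible; bilateral
#'   symmetry is not applicable and the template carries no pairs.
#'
#' Landmark indices are 1-based everywhere in files, templates and
#' documentation; pairing is stored with the lower index conventionally on
#' the left side.
#'
#' @param name Template name, one of `"cranium36"` or `"mandible9"`.
#' @return An object of class `landmark_template`: a list with elements
#'   `structure_name`, `landmark_names` (character), `dimension` (always 3),
#'   `pairs` (integer matrix with columns `left`, `right`; zero rows when
#'   symmetry is not applicable) and `midline` (integer vector; for one-sided
#'   templates this is empty and all landmarks are unpaired).
#' @examples
#' tpl <- load_template("cranium36")
#' nrow(tpl$pairs)     # 14 bilateral pairs
#' length(tpl$midline) # 8 midline landmarks
#' @export
load_template <- function(name) {
  switch(name,
    cranium36 = new_template(
      structure_name = "cranium",
      landmark_names = c(
        "interpremaxillary_suture_ant",        # 1
        "premaxillo_maxillary_suture_L",       # 2
        "premaxillo_maxillary_suture_R",       # 3
        "internasal_suture_ant",               # 4
        "internasal_interfrontal_int",         # 5
        "lacrimal_frontal_maxilla_L",          # 6
        "lacrimal_frontal_maxilla_R",          # 7
        "zygomatic_frontal_process_L",         # 8
        "zygomatic_frontal_process_R",         # 9
        "postorbital_process_L",               # 10
        "postorbital_process_R",               # 11
        "interparietal_interfrontal_int",      # 12
        "ext_auditory_meatus_post_L",          # 13
        "ext_auditory_meatus_post_R",          # 14
        "parietal_squamosal_supraocc_L",       # 15
        "parietal_squamosal_supraocc_R",       # 16
        "ext_occipital_protuberance",          # 17
        "canine_alveolus_post_L",              # 18
        "canine_alveolus_post_R",              # 19
        "toothrow_post_L",                     # 20
        "toothrow_post_R",                     # 21
        "palatine_concavity_post",             # 22
        "jugo_maxillary_suture_L",             # 23
        "jugo_maxillary_suture_R",             # 24
        "jugo_squamosal_suture_L",             # 25
        "jugo_squamosal_suture_R",             # 26
        "basiocc_basisphenoid_bulla_L",        # 27
        "basiocc_basisphenoid_bulla_R",        # 28
        "mastoid_process_L",                   # 29
        "mastoid_process_R",                   # 30
        "postglenoid_process_L",               # 31
        "postglenoid_process_R",               # 32
        "occipital_condyle_lat_L",             # 33
        "occipital_condyle_lat_R",             # 34
        "foramen_magnum_antvent",              # 35
        "foramen_magnum_postdors"              # 36
      ),
      pairs = cbind(
        left  = c(2L, 6L, 8L, 10L, 13L, 15L, 18L, 20L, 23L, 25L, 27L, 29L, 31L, 33L),
        right = c(3L, 7L, 9L, 11L, 14L, 16L, 19L, 21L, 24L, 26L, 28L, 30L, 32L, 34L)
      ),
      midline = c(1L, 4L, 5L, 12L, 17L, 22L, 35L, 36L)
    ),
    mandible9 = new_template(
      structure_name = "mandible",
      landmark_names = c(
        "symphysis_antvent",            # 1
        "canine_alveolus_postdors",     # 2
        "p4_alveolar_ant",              # 3
        "toothrow_post",                # 4
        "coronoid_process_post",        # 5
        "condyloid_process_lat",        # 6
        "condyloid_process_med",        # 7
        "angular_process_tip",          # 8
        "symphyseal_region_vent"        # 9
      ),
      pairs = cbind(left = integer(0), right = integer(0)),
      midline = integer(0)
    ),
    stop("template not found: ", name, " (available: cranium36, mandible9)",
         call. = FALSE)
  )
}

new_template <- function(structure_name, landmark_names, pairs, midline) {
  tpl <- structure(
    list(structure_name = structure_name,
         landmark_names = landmark_names,
         dimension = 3L,
         pairs = pairs,
         midline = as.integer(midline)),
    class = "landmark_template"
  )
  validate_template(tpl)
  tpl
}

# Pair/midline partition must be exhaustive and disjoint when symmetry
# applies; one-sided templates carry neither pairs nor midline.
validate_template <- function(tpl) {
  k <- length(tpl$landmark_names)
  idx <- c(as.vector(tpl$pairs), tpl$midline)
  if (length(idx)) {
    if (anyDuplicated(idx))
      stop("template invalid: landmark in more than one pair/midline slot",
           call. = FALSE)
    if (any(idx < 1L | idx > k))
      stop("template invalid: landmark index out of range", call. = FALSE)
    if (length(idx) != k)
      stop("template invalid: pair/midline partition does not cover all ",
           k, " landmarks", call. = FALSE)
  }
  invisible(tpl)
}

#' @export
print.landmark_template <- function(x, ...) {
  cat("Landmark template '", x$structure_name, "': ",
      length(x$landmark_names), " landmarks in ", x$dimension, "D, ",
      nrow(x$pairs), " bilateral pairs, ", length(x$midline),
      " midline landmarks\n", sep = "")
  invisible(x)
}

# TRUE when the template supports object-symmetry decomposition.
has_symmetry <- function(tpl) nrow(tpl$pairs) > 0L

#' Study design table
#'
#' Packaged specimen counts of the cranial/mandibular bear study design the
#' synthetic scenarios emulate: four species (brown bear *U. arctos*, American
#' black bear *U. americanus*, polar bear *U. maritimus* and the extinct cave
#' bear *U. spelaeus*), two age classes, two structures. Juveniles are present
#' only for *arctos* and *spelaeus*.
#'
#' @return A data frame with columns `species`, `structure`, `age_class`, `n`.
#'   Column sums reproduce the study totals: 253 crania and 183 mandibles.
#' @examples
#' d <- study_design_table()
#' sum(d$n[d$structure == "cranium"])  # 253
#' @export
study_design_table <- function() {
  data.frame(
    species   = rep(c("arctos", "americanus", "maritimus", "spelaeus"), each = 4L),
    structure = rep(c("cranium", "cranium", "mandible", "mandible"), times = 4L),
    age_class = rep(c("adult", "juvenile"), times = 8L),
    n = c(56L, 27L, 56L, 21L,   # arctos
          28L,  0L, 28L,  0L,   # americanus
          42L,  0L, 43L,  0L,   # maritimus
          97L,  3L, 31L,  4L),  # spelaeus
    stringsAsFactors = FALSE
  )
}
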