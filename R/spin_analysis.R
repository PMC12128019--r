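#' Per-atom Mulliken spin populations with fragment labels
#'
#' Validates a table of per-atom Mulliken spin populations -- the per-atom
#' partition of the unpaired-electron density, which sums to 2 for a triplet
#' -- with each atom assigned to exactly one molecular fragment (e.g. one
#' nucleobase of a stacked dimer). Classification of the triplet as localized
#' or delocalized then works on fragment-level sums.
#'
#' @param data Data frame with columns `atom_id`, `spin`, `fragment`.
#' @param total_spin Expected total spin (2 for a triplet).
#' @param tolerance Allowed deviation of `sum(spin)` from `total_spin`.
#' @return A tibble of class `spin_populations` with attribute `total_spin`.
#' @export
#' @examples
#' pops <- spin_populations(tibble::tibble(
#'   atom_id = c("C1", "C2", "C3"), spin = c(1.2, 0.76, 0.04),
#'   fragment = c("T1", "T1", "T2")))
#' fragment_spins(pops)
spin_populations <- function(data, total_spin = 2, tolerance = 0.05) {
  stopifnot(total_spin > 0, tolerance >= 0)
  data <- as_tibble(data)
  req <- c("atom_id", "spin", "fragment")
  if (!all(req %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("Empty spin-population table.")
  if (anyNA(data$spin) || any(!is.finite(data$spin))) {
    abort("Spin populations must be finite.")
  }
  if (anyNA(data$fragment) || any(data$fragment == "")) {
    abort("Every atom must be assigned to a fragment.")
  }
  if (anyDuplicated(data$atom_id)) abort("Duplicate atom_id entries.")
  s <- sum(data$spin)
  if (abs(s - total_spin) > tolerance) {
    abort(sprintf(
      "Total spin %.4f deviates from %.4f by more than the tolerance %.4f.",
      s, total_spin, tolerance))
  }
  structure(data, total_spin = total_spin,
            class = c("spin_populations", class(data)))
}

#' Fragment-level spin sums
#'
#' Repartitions the atomic spin populations into per-fragment sums; the sum
#' over fragments equals the sum over atoms exactly.
#'
#' @param pops A [spin_populations()] table.
#' @return A tibble with columns `fragment`, `spin`, sorted by decreasing
#'   spin, carrying the `total_spin` attribute forward.
#' @export
fragment_spins <- function(pops) {
  stopifnot(inherits(pops, "spin_populations"))
  out <- as_tibble(pops) |>
    dplyr::group_by(.data$fragment) |>
    dplyr::summarise(spin = sum(.data$spin), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$spin))
  attr(out, "total_spin") <- attr(pops, "total_spin")
  out
}

#' Classify a triplet as localized or delocalized
#'
#' The localization index is the largest fragment's share of the total spin,
#' \eqn{\max_f S_f / S_{tot}}; the state is called `localized` when the index
#' reaches the threshold, `delocalized` otherwise. A fully localized dimer
#' triplet has index near 1 (all two unpaired electrons on one nucleobase), a
#' symmetric excimer-like state has index 0.5. The threshold defaults to
#' 0.75, midway between those regimes; it is a reporting convention, not a
#' physical constant, and must stay in (0.5, 1\].
#'
#' @param fragment_sums A tibble from [fragment_spins()], or a named numeric
#'   vector of fragment spin sums.
#' @param total_spin Total spin; defaults to the table's attribute, else the
#'   sum of the fragment sums.
#' @param threshold Localization threshold on the index, in (0.5, 1\].
#' @return A list of class `spin_localization` with `label`
#'   (`"localized"`/`"delocalized"`), `localization_index`,
#'   `dominant_fragment`, `fragment_sums`, `threshold`, `total_spin`.
#' @export
classify_localization <- function(fragment_sums, total_spin = NULL,
                                  threshold = 0.75) {
  if (is.numeric(fragment_sums) && !is.null(names(fragment_sums))) {
    fragment_sums <- tibble(fragment = names(fragment_sums),
                            spin = as.numeric(fragment_sums))
  }
  fragment_sums <- as_tibble(fragment_sums)
  stopifnot(all(c("fragment", "spin") %in% names(fragment_sums)),
            nrow(fragment_sums) >= 1)
  if (is.null(total_spin)) {
    total_spin <- attr(fragment_sums, "total_spin") %||%
      sum(fragment_sums$spin)
  }
  if (total_spin <= 0) abort("`total_spin` must be > 0.")
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must lie in (0.5, 1].")
  }
  i_max <- which.max(fragment_sums$spin)
  index <- fragment_sums$spin[i_max] / total_spin
  structure(
    list(label = if (index >= threshold) "localized" else "delocalized",
         localization_index = index,
         dominant_fragment = fragment_sums$fragment[i_max],
         fragment_sums = fragment_sums,
         threshold = threshold,
         total_spin = total_spin),
    class = "spin_localization")
}

#' @export
print.spin_localization <- function(x, ...) {
  cat(sprintf("<spin_localization> %s (index %.3f, threshold %.2f) on '%s'\n",
              x$label, x$localization_index, x$threshold,
              x$dominant_fragment))
  invisible(x)
}

#' Read spin populations from delimited text
#'
#' Reads a tab- or comma-delimited table with columns `atom_id`, `spin`,
#' `fragment` and validates it with [spin_populations()].
#'
#' @param path File path.
#' @inheritParams spin_populations
#' @return A [spin_populations()] tibble.
#' @export
read_spin_populations <- function(path, total_spin = 2, tolerance = 0.05) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  spin_populations(df, total_spin = total_spin, tolerance = tolerance)
}

#' Write a spin-localization result as JSON
#'
#' Emits `{fragment_sums, localization_index, label, threshold, total_spin}`.
#'
#' @param result A `spin_localization` from [classify_localization()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spin_json <- function(result, path) {
  stopifnot(inherits(result, "spin_localization"))
  jsonlite::write_json(
    list(fragment_sums = setNames(as.list(result$fragment_sums$spin),
                                  result$fragment_sums$fragment),
         localization_index = result$localization_index,
         label = result$label,
         threshold = result$threshold,
         total_spin = result$total_spin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
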