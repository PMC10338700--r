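#' Age/sex group scheme
#'
#' Defines the demographic strata (bands) used throughout the planner. Bands
#' are indexed k = 1..K with the convention that bands 1..K/2 are male and
#' bands K/2+1..K are female, paired by age: band k and band k + K/2 carry the
#' same age label. The default is the 12-band scheme used for invitations to a
#' multi-cancer screening trial: six age bands (50-54, 55-59, 60-64, 65-69,
#' 70-74, 75-77) crossed with sex.
#'
#' @param age_labels Character vector of ordered age-band labels; one per age
#'   band, shared by the male and female halves.
#' @return An object of class \code{group_scheme} with elements \code{K}
#'   (total band count), \code{age_labels}, \code{sex} (per-band sex code) and
#'   \code{age_band} (per-band age index 1..K/2).
#' @examples
#' sc <- group_scheme()
#' sc$K              # 12
#' band_labels(sc)   # "M 50-54" ... "F 75-77"
#' @export
group_scheme <- function(age_labels = c("50-54", "55-59", "60-64",
                                        "65-69", "70-74", "75-77")) {
  stopifnot(is.character(age_labels), length(age_labels) >= 1,
            !anyDuplicated(age_labels))
  K <- 2L * length(age_labels)
  structure(list(
    K = K,
    age_labels = age_labels,
    sex = rep(c("M", "F"), each = K / 2L),
    age_band = rep(seq_len(K / 2L), times = 2L)
  ), class = "group_scheme")
}

#' @rdname group_scheme
#' @param scheme A \code{group_scheme}.
#' @export
band_labels <- function(scheme) {
  paste(scheme$sex, scheme$age_labels[scheme$age_band])
}

#' @export
print.group_scheme <- function(x, ...) {
  cat("Group scheme:", x$K, "bands (", x$K / 2L, "age bands x 2 sexes )\n")
  cat("  ", paste(band_labels(x), collapse = ", "), "\n")
  invisible(x)
}

# Index of the female band paired with male band k (k must be <= K/2)
paired_band <- function(scheme, k) k + scheme$K / 2L

# Map a J x K matrix to J x (K/2) by summing male and female columns per age band
collapse_sexes <- function(m, scheme) {
  H <- scheme$K / 2L
  m[, seq_len(H), drop = FALSE] + m[, H + seq_len(H), drop = FALSE]
}
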