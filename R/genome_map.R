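#' Chromosome model: arm lengths and recombination-intensity gradient
#'
#' Describes one Triticeae-like chromosome: physical arm lengths in Mb and a
#' recombination-intensity function c(x) in cM/Mb over the relative arm
#' position x in `[0, 1]` (0 = centromere, 1 = telomere), parameterized as the
#' positive exponential \eqn{c(x) = a e^{b x}}. Recombination in Triticeae
#' rises steeply from centromere to telomere; the defaults span cM/Mb ratios
#' from `a` = 0.01 at the centromere to 0.85 at the telomere (about two
#' orders of magnitude, as observed along wheat chromosome 3B), i.e.
#' `b = log(85)`.
#'
#' @param arm_length_short,arm_length_long Arm lengths in Mb; defaults 388
#'   (short) and 437 (long).
#' @param a Intensity at the centromere, cM/Mb; must be >= 0.
#' @param b Exponential slope over relative position; `b = 0` gives a uniform
#'   gradient.
#' @return An object of class `chromosome_model`.
#' @export
chromosome_model <- function(arm_length_short = 388, arm_length_long = 437,
                             a = 0.01, b = log(85)) {
  if (arm_length_short <= 0 || arm_length_long <= 0)
    stop("arm lengths must be positive")
  if (a < 0) stop("intensity parameter 'a' must be nonnegative")
  structure(list(arm_length_short = arm_length_short,
                 arm_length_long = arm_length_long, a = a, b = b),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat("Chromosome model: arms", x$arm_length_short, "/", x$arm_length_long,
      "Mb (short/long); c(x) =", x$a, "* exp(", format(x$b, digits = 4),
      "* x) cM/Mb\n")
  invisible(x)
}

arm_length <- function(model, arm) {
  ifelse(arm == "short", model$arm_length_short,
  ifelse(arm == "long", model$arm_length_long, NA_real_))
}

#' Genetic distance from the centromere
#'
#' Integrates the recombination intensity along the arm and scales by the
#' physical arm length:
#' \deqn{g(x) = L \int_0^x c(u)\,du = L\,a\,(e^{b x} - 1)/b,}
#' with the limit \eqn{L a x} as b tends to 0. `g(0) = 0` and g is strictly
#' increasing in x whenever `a > 0`.
#'
#' @param x Relative distance to the centromere, in `[0, 1]` (vectorized).
#' @param arm `"short"` or `"long"` (recycled against `x`).
#' @param model A [chromosome_model()].
#' @return Genetic distance(s) in cM.
#' @examples
#' genetic_distance(0.5, "long", chromosome_model())
#' @export
genetic_distance <- function(x, arm, model = chromosome_model()) {
  stopifnot(inherits(model, "chromosome_model"))
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("relative position x must lie in [0, 1]")
  bad <- !is.na(arm) & !(arm %in% c("short", "long"))
  if (any(bad)) stop("arm must be 'short' or 'long'")
  L <- arm_length(model, arm)
  if (abs(model$b) < 1e-12) {
    L * model$a * x
  } else {
    L * model$a * (exp(model$b * x) - 1) / model$b
  }
}

#' Signed genetic coordinate along the chromosome
#'
#' Positive genetic distances on the long arm, negative on the short arm,
#' zero at the centromere, so that coordinates increase monotonically from the
#' short-arm telomere through the centromere to the long-arm telomere.
#'
#' @inheritParams genetic_distance
#' @return Signed genetic coordinate(s) in cM.
#' @export
signed_coordinate <- function(x, arm, model = chromosome_model()) {
  g <- genetic_distance(x, arm, model)
  ifelse(arm == "short", -g, g)
}

#' Classify a locus as centromeric or telomeric
#'
#' Centromeric when the relative physical distance to the centromere is below
#' 70% of the arm, telomeric above 70%. Exactly 70% is classified as
#' centromeric (boundary convention; no locus in the packaged annotations
#' sits on the boundary).
#'
#' @param x Relative distance(s) to the centromere in `[0, 1]`.
#' @return Character vector, `"centromeric"` or `"telomeric"` (`NA` in,
#'   `NA` out).
#' @examples
#' classify_region(c(0.352, 0.705, 0.976))
#' @export
classify_region <- function(x) {
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("relative position x must lie in [0, 1]")
  ifelse(is.na(x), NA_character_,
         ifelse(x > 0.70, "telomeric", "centromeric"))
}

#' Pairwise genetic-distance matrix between loci
#'
#' Unsigned separation `|s_i - s_j|` of the signed genetic coordinates of all
#' locus pairs. Loci with a missing arm or position are excluded with a
#' warning.
#'
#' @param loci Data frame with columns `locus`, `arm` and
#'   `rel_dist_centromere` (see [read_locus_annotations()]).
#' @param model A [chromosome_model()].
#' @return Symmetric matrix in cM with zero diagonal, loci as dimnames, and
#'   the signed coordinates in the `"signed_coordinate"` attribute.
#' @export
pairwise_genetic_distance <- function(loci, model = chromosome_model()) {
  need <- c("locus", "arm", "rel_dist_centromere")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  usable <- !is.na(loci$arm) & !is.na(loci$rel_dist_centromere) &
    loci$arm %in% c("short", "long")
  if (any(!usable))
    warning(sum(!usable), " locus/loci without a mapped position excluded: ",
            paste(loci$locus[!usable], collapse = ", "), call. = FALSE)
  loci <- loci[usable, , drop = FALSE]
  s <- signed_coordinate(loci$rel_dist_centromere, loci$arm, model)
  G <- abs(outer(s, s, "-"))
  dimnames(G) <- list(loci$locus, loci$locus)
  attr(G, "signed_coordinate") <- stats::setNames(s, loci$locus)
  G
}

#' Read a locus-annotation table
#'
#' Tab-separated annotations with one row per locus. Required columns:
#' `locus`, `length_bp`, `chromosome`, `arm` (`short`/`long`/`NA`),
#' `rel_dist_centromere` (relative distance to the centromere in `[0, 1]`,
#' `NA` when unmapped), `region` (`centromeric`/`telomeric`/`NA`),
#' `evo_rate` (relative evolutionary rate), `alpha` (gamma shape),
#' `prop_variable`, and the per-locus triplet distances `td_supermatrix` and
#' `td_bucky`. The packaged annotation table for the 27 Triticeae loci is
#' returned by default.
#'
#' @param file Path to the TSV; defaults to the packaged Triticeae table.
#' @return A data frame of locus annotations.
#' @export
read_locus_annotations <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "triticeae_loci.tsv", package = "tripdist",
                        mustWork = TRUE)
  ann <- utils::read.delim(file, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("locus", "length_bp", "chromosome", "arm", "rel_dist_centromere",
            "region", "evo_rate", "alpha", "prop_variable",
            "td_supermatrix", "td_bucky")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  x <- ann$rel_dist_centromere
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("rel_dist_centromere outside [0, 1]")
  ann
}
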