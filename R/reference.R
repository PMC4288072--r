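## Published reference statistics from a 122-narrative FAERS annotation
## study (two independent annotators plus a tiebreaker; nine entity
## classes). Bundled so that consistency identities between the reported
## quantities can be re-derived with this package's own metric functions.

#' Reference statistics from a 122-narrative FAERS annotation study
#'
#' Returns per-class and corpus-level statistics reported for a
#' dual-annotated corpus of 122 FAERS (FDA Adverse Event Reporting
#' System) narratives: annotation counts on the four annotation sets
#' (\code{AnnPhy}, \code{AnnLing}, their agreed intersection \code{Comb},
#' and the tiebroken set \code{Tie}), Cohen's kappa under strict and
#' unstrict matching, and the per-class F1 of the all-features CRF tagger
#' evaluated on \code{Comb} by ten-fold cross-validation.
#'
#' These numbers are the calibration targets for the synthetic corpus
#' generator: [generator_config()] defaults its class weights to the
#' \code{Comb} counts and its disagreement-perturbation mixture to the
#' \code{disagreements} shares.
#'
#' @return A list with components:
#'   \describe{
#'     \item{per_class}{data.frame, one row per entity class in
#'       [entity_classes()] order, with columns \code{entity_class},
#'       \code{count_annphy}, \code{count_annling}, \code{count_comb},
#'       \code{count_tie}, \code{kappa_strict}, \code{kappa_unstrict},
#'       \code{f1_all_features}.}
#'     \item{combined_tagger}{reported overall precision, recall and F1
#'       of the all-features CRF on the \code{Comb} set.}
#'     \item{disagreements}{token-level disagreement counts between the
#'       two annotators, split into \code{boundary}, \code{missed} and
#'       \code{category} causes, plus their \code{total}.}
#'   }
#' @examples
#' stats <- faers_reference_stats()
#' stats$per_class$entity_class
#' stats$disagreements$total
#' @export
faers_reference_stats <- function() {
  path <- aet_resource("faers_reference_stats.tsv")
  per_class <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(per_class$entity_class, entity_classes()))
  list(
    per_class = per_class,
    combined_tagger = list(precision = 0.81, recall = 0.66, f1 = 0.73),
    disagreements = list(boundary = 412L, missed = 2355L,
                         category = 188L, total = 2955L)
  )
}
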