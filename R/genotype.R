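#' The genotype rule cascade
#'
#' Ordered decision rules classifying a non-reference insertion site from
#' its average flanker count F (mean of left and right flanker counts, so
#' possibly half-integral) and spanner count S.  The first satisfied rule
#' wins:
#'
#' i.   all flankers and no spanners (S = 0): homozygous;
#' ii.  five or more flankers and fewer than five spanners: homozygous with
#'      a somatic excision event;
#' iii. spanners at most 20% of flankers and no more than 10 spanners:
#'      homozygous with a somatic excision event;
#' iv.  no more than 2 flankers and more than 10 spanners: somatic
#'      insertion;
#' v.   |F - S| at most 10 more than the average read count (F+S)/2:
#'      heterozygous;
#' vi.  both flankers and spanners each more than 10: heterozygous;
#' vii. 10 or fewer flankers and |S - F| greater than (F+S)/2: somatic
#'      insertion;
#' viii. anything else: other.
#'
#' Comparisons are exact: threshold tests are phrased over integers and
#' dyadic rationals (F is a half-integer), so no floating-point rounding can
#' flip a boundary case.
#'
#' @return an ordered list of rules, each with `name`, `genotype`, and a
#'   predicate `test(F, S)`.
#' @export
genotype_rules <- function() {
  list(
    list(name = "i", genotype = "homozygous",
         test = function(F, S) S == 0),
    list(name = "ii", genotype = "homozygous_somatic_excision",
         test = function(F, S) F >= 5 & S < 5),
    list(name = "iii", genotype = "homozygous_somatic_excision",
         test = function(F, S) S <= 10 & 5 * S <= F),
    list(name = "iv", genotype = "somatic_insertion",
         test = function(F, S) F <= 2 & S > 10),
    list(name = "v", genotype = "heterozygous",
         test = function(F, S) 2 * abs(F - S) <= F + S + 20),
    list(name = "vi", genotype = "heterozygous",
         test = function(F, S) F > 10 & S > 10),
    list(name = "vii", genotype = "somatic_insertion",
         test = function(F, S) F <= 10 & 2 * abs(S - F) > F + S),
    list(name = "viii", genotype = "other",
         test = function(F, S) rep(TRUE, length(F)))
  )
}

#' Classify the genotype of an insertion site
#'
#' Applies the rule cascade of [genotype_rules()] in order and returns the
#' first satisfied rule's genotype.  Vectorized over sites.
#'
#' @param F average flanker count(s), (left + right) / 2; must be positive
#'   (a site only exists through flanker evidence).
#' @param S spanner count(s), non-negative integers.
#' @param rules the rule cascade (exposed for order-sensitivity analysis;
#'   default [genotype_rules()]).
#' @return data frame with columns `genotype` and `rule`.
#' @examples
#' classify_genotype(27.5, 0)   # homozygous (rule i)
#' classify_genotype(13.5, 8)   # heterozygous (rule v)
#' classify_genotype(1.5, 21)   # somatic insertion (rule iv)
#' @export
classify_genotype <- function(F, S, rules = genotype_rules()) {
  stopifnot(length(F) == length(S), all(F > 0), all(S >= 0))
  genotype <- rep(NA_character_, length(F))
  rule <- rep(NA_character_, length(F))
  todo <- rep(TRUE, length(F))
  for (r in rules) {
    if (!any(todo)) break
    hit <- todo & r$test(F, S)
    genotype[hit] <- r$genotype
    rule[hit] <- r$name
    todo <- todo & !hit
  }
  data.frame(genotype = genotype, rule = rule, stringsAsFactors = FALSE)
}
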