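# Targeted MRM transition design from adduct hypotheses.
#
# DNA adducts are built from three chemically stable subunits - deoxyribose,
# DNA base and (transformed) xenobiotic - so their cleavages make reliable
# product ions for multiple reaction monitoring even when no reference
# compound exists.

#' Design MRM transitions for an adduct hypothesis
#'
#' For a nucleoside-target hypothesis: the deoxyribose loss
#' (`[M+H]+ -> [M+H-116.0473]+`, label `loss_dR`), the protonated target
#' nucleoside (`nucleoside_ion`), the protonated base (`base_ion`) and the
#' protonated transformed xenobiotic (`metabolite_ion`). With
#' `include_insource_species`, transitions for the co-occurring depurinated
#' in-source species are added: its precursor is `[M+H-116.0473]+` and its
#' product the base cleavage (`base_cleavage`). For a base-target
#' (depurinated) hypothesis only `base_ion` and `metabolite_ion` apply;
#' requesting `loss_dR` there is an error.
#'
#' @param h One hypothesis: a one-row data frame from
#'   [enumerate_hypotheses()] / [adduct_hypothesis()].
#' @param include_insource_species Also emit the depurinated-species
#'   transitions (default `TRUE` for nucleoside targets).
#' @param labels Optional subset of labels to generate; an explicit request
#'   for `loss_dR` on a base-only hypothesis is an error.
#' @return Data frame of transitions: `compound`, `q1`, `q3`, `label`.
#' @examples
#' h <- adduct_hypothesis("C12H16O3",
#'                        list(biotransformations()$epoxidation),
#'                        target = "dA", parent_name = "AS")
#' design_transitions(h)
#' @export
design_transitions <- function(h, include_insource_species = TRUE,
                               labels = NULL) {
  stopifnot(is.data.frame(h), nrow(h) == 1L)
  tg <- dna_targets()
  target <- tg[match(h$target, tg$name), ]
  base_f <- tg$formula[match(target$base, tg$name)]
  adduct <- parse_formula(h$adduct_formula)
  q1 <- protonated_mz(adduct)
  # transformed xenobiotic recovered from the subunit arithmetic:
  # metabolite = adduct - target + binding_loss
  metabolite <- formula_subtract(adduct, target$formula)
  if (h$binding_loss != "none")
    metabolite <- formula_add(metabolite, h$binding_loss)
  dr <- monoisotopic_mass("C5H8O3")
  rows <- list()
  add <- function(q1v, q3v, label)
    rows[[length(rows) + 1L]] <<- data.frame(compound = h$name, q1 = q1v,
                                             q3 = q3v, label = label)
  if (!is.null(labels) && "loss_dR" %in% labels && !target$is_nucleoside)
    stop("loss_dR transition requires a nucleoside target")
  if (target$is_nucleoside) {
    add(q1, q1 - dr, "loss_dR")
    add(q1, protonated_mz(target$formula), "nucleoside_ion")
  }
  add(q1, protonated_mz(base_f), "base_ion")
  add(q1, protonated_mz(metabolite), "metabolite_ion")
  if (include_insource_species && target$is_nucleoside) {
    q1_dep <- q1 - dr
    add(q1_dep, q1_dep - monoisotopic_mass(base_f), "base_cleavage")
  }
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out <- out[out$label %in% labels, , drop = FALSE]
  out <- out[out$q3 > 0 & out$q3 < out$q1 + 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a transition list to CSV
#'
#' @param transitions Data frame from [design_transitions()] (one or more
#'   hypotheses `rbind`ed together).
#' @param path Output CSV path.
#' @param mode `"accurate"` prints q1/q3 to 4 d.p.; `"unit"` reproduces
#'   vendor-style unit-resolution settings by truncating to the integer
#'   below and printing 1 d.p. (e.g. 444.19 becomes 444.0).
#' @return `path`, invisibly.
#' @export
export_transition_list <- function(transitions, path,
                                   mode = c("accurate", "unit")) {
  mode <- match.arg(mode)
  if (is.null(transitions) || !nrow(transitions))
    stop("empty transition list")
  fmt <- function(x) if (mode == "accurate") sprintf("%.4f", x)
                     else sprintf("%.1f", trunc(x))
  out <- data.frame(compound = transitions$compound,
                    q1 = fmt(transitions$q1), q3 = fmt(transitions$q3),
                    label = transitions$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
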