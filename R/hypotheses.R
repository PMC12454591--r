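# Biotransformation arithmetic, DNA targets and adduct hypothesis enumeration.
#
# An adduct hypothesis follows the subunit logic of DNA adducts: a (possibly
# biotransformed) xenobiotic bound to a DNA base or 2'-deoxynucleoside,
# optionally losing a small molecule (e.g. H2O) on bond formation. Nucleoside
# targets model intact adducts; base targets model depurinated adducts.

#' Define a biotransformation step
#'
#' A step is a signed composition change: atoms gained and atoms lost.
#' Applying then reverting a step restores the original formula.
#'
#' @param name Step label.
#' @param gain,loss Formula strings (or `elemental_formula`) of atoms added /
#'   removed; `NULL` for none.
#' @return A `biotransformation` object.
#' @export
biotransformation <- function(name, gain = NULL, loss = NULL) {
  structure(list(
    name = name,
    gain = if (is.null(gain)) .new_formula(integer(0)) else .as_formula(gain),
    loss = if (is.null(loss)) .new_formula(integer(0)) else .as_formula(loss)
  ), class = "biotransformation")
}

#' Default biotransformation library
#'
#' Phase-I style activation steps commonly preceding DNA binding:
#' epoxidation and hydroxylation (+O), hydration (+H2O), dehydration (-H2O),
#' desaturation (-H2), and dihydrodiol formation (+O +H2O, a composite of
#' epoxidation and hydrolysis). Sulfation is treated as an activating step
#' that leaves no mass trace in the final adduct (the sulfate is lost before
#' DNA binding), so no +/-SO3 step is included by default.
#'
#' @return Named list of [biotransformation()] steps.
#' @export
biotransformations <- function() {
  list(
    epoxidation   = biotransformation("epoxidation", gain = "O"),
    hydroxylation = biotransformation("hydroxylation", gain = "O"),
    hydration     = biotransformation("hydration", gain = "H2O"),
    dehydration   = biotransformation("dehydration", loss = "H2O"),
    desaturation  = biotransformation("desaturation", loss = "H2"),
    dihydrodiol   = biotransformation("dihydrodiol", gain = "H2O2")
  )
}

#' Apply a chain of biotransformation steps
#'
#' @param parent Parent compound formula (string or `elemental_formula`).
#' @param chain List of [biotransformation()] steps, applied in order.
#' @param max_chain Maximum allowed chain length (guard; default 3 covers
#'   e.g. a two-fold epoxidation with intermediate hydrolysis).
#' @return The transformed `elemental_formula`; errors if any intermediate
#'   element count would become negative.
#' @examples
#' apply_chain("C12H16O3", list(biotransformations()$epoxidation))
#' @export
apply_chain <- function(parent, chain = list(), max_chain = 3L) {
  f <- .as_formula(parent)
  if (length(chain) > max_chain)
    stop("chain longer than max_chain (", max_chain, ")")
  for (step in chain) {
    stopifnot(inherits(step, "biotransformation"))
    f <- formula_add(f, step$gain)
    f <- formula_subtract(f, step$loss)   # errors on impossible chemistry
  }
  f
}

#' Revert a single biotransformation step
#'
#' @param f Formula after the step.
#' @param step A [biotransformation()].
#' @return The formula before the step.
#' @export
revert_step <- function(f, step) {
  stopifnot(inherits(step, "biotransformation"))
  formula_subtract(formula_add(.as_formula(f), step$loss), step$gain)
}

#' DNA bases and 2'-deoxynucleosides available as adduct targets
#'
#' Base targets (Gua, Ade, Cyt, Thy) model depurinated adducts; nucleoside
#' targets (dG, dA, dC, dT) model intact adducts. For every base/nucleoside
#' pair the composition difference is the deoxyribose remainder C5H8O3
#' (116.0473 Da), the diagnostic neutral loss of DNA adduct fragmentation.
#'
#' @return A data frame with columns `name`, `formula` (Hill string),
#'   `is_nucleoside`, and `base` (the base moiety of a nucleoside, itself
#'   for a base).
#' @export
dna_targets <- function() {
  data.frame(
    name = c("Gua", "Ade", "Cyt", "Thy", "dG", "dA", "dC", "dT"),
    formula = c("C5H5N5O", "C5H5N5", "C4H5N3O", "C5H6N2O2",
                "C10H13N5O4", "C10H13N5O3", "C9H13N3O4", "C10H14N2O5"),
    is_nucleoside = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    base = c("Gua", "Ade", "Cyt", "Thy", "Gua", "Ade", "Cyt", "Thy"),
    stringsAsFactors = FALSE
  )
}

# composition of the deoxyribose remainder lost on depurination / dR cleavage
.deoxyribose_loss <- function() parse_formula("C5H8O3")

#' Construct a single adduct hypothesis
#'
#' @param parent Parent compound formula (string or `elemental_formula`).
#' @param chain List of [biotransformation()] steps applied to the parent.
#' @param target One row of [dna_targets()] (or a target name).
#' @param binding_loss Formula removed on bond formation: `NULL` (direct
#'   addition, the default) or e.g. `"H2O"`.
#' @param parent_name Label used to build the hypothesis name.
#' @return A one-row data frame with columns `name`, `parent_formula`,
#'   `chain`, `target`, `binding_loss`, `adduct_formula`, `expected_mz`,
#'   `n_steps`, `is_nucleoside`, `base`.
#' @examples
#' adduct_hypothesis("C3H6O2", target = "Gua")  # glycidol-Gua, 226.0935
#' @export
adduct_hypothesis <- function(parent, chain = list(), target,
                              binding_loss = NULL, parent_name = "parent") {
  if (is.character(target)) {
    tg <- dna_targets()
    hit <- match(target, tg$name)
    if (is.na(hit)) stop("unknown DNA target: ", target)
    target <- tg[hit, ]
  }
  metabolite <- apply_chain(parent, chain, max_chain = max(3L, length(chain)))
  adduct <- formula_add(metabolite, target$formula)
  bl_label <- "none"
  if (!is.null(binding_loss)) {
    adduct <- formula_subtract(adduct, binding_loss)
    bl_label <- format_formula(.as_formula(binding_loss))
  }
  chain_label <- paste(vapply(chain, `[[`, "", "name"), collapse = "+")
  nm <- paste0(parent_name,
               if (nzchar(chain_label)) paste0("+", chain_label) else "",
               "-", target$name,
               if (bl_label != "none") paste0("(-", bl_label, ")") else "")
  data.frame(
    name = nm,
    parent_formula = format_formula(.as_formula(parent)),
    chain = chain_label,
    target = target$name,
    binding_loss = bl_label,
    adduct_formula = format_formula(adduct),
    expected_mz = protonated_mz(adduct),
    n_steps = length(chain),
    is_nucleoside = target$is_nucleoside,
    base = target$base,
    stringsAsFactors = FALSE
  )
}

# all multisets of step indices of size 0..max_chain
.chain_multisets <- function(n_steps, max_chain) {
  out <- list(integer(0))
  if (max_chain < 1L || n_steps < 1L) return(out)
  grow <- list(integer(0))
  for (k in seq_len(max_chain)) {
    nxt <- list()
    for (ms in grow) {
      lo <- if (length(ms)) ms[length(ms)] else 1L
      for (i in lo:n_steps) nxt[[length(nxt) + 1L]] <- c(ms, i)
    }
    out <- c(out, nxt)
    grow <- nxt
  }
  out
}

#' Enumerate adduct hypotheses for a parent compound
#'
#' Builds every distinct combination of a biotransformation chain (as a
#' multiset up to `max_chain` steps), a DNA target, and a binding loss,
#' deduplicated by adduct formula (keeping the fewest-step variant) and
#' sorted by expected m/z.
#'
#' @param parent Parent compound formula (string or `elemental_formula`).
#' @param steps Named list of allowed [biotransformation()] steps.
#' @param targets Subset of [dna_targets()] (data frame or character names).
#' @param max_chain Maximum number of biotransformation steps (default 3).
#' @param binding_losses Character vector of binding-loss options; `"none"`
#'   means direct addition.
#' @param parent_name Label for hypothesis names.
#' @return Data frame of hypotheses (see [adduct_hypothesis()]), sorted by
#'   `expected_mz`.
#' @examples
#' h <- enumerate_hypotheses("C3H6O2", steps = list(), targets = "Gua",
#'                           max_chain = 0, parent_name = "glycidol")
#' h$expected_mz  # 226.0935
#' @export
enumerate_hypotheses <- function(parent, steps = biotransformations(),
                                 targets = dna_targets(), max_chain = 3L,
                                 binding_losses = c("none", "H2O"),
                                 parent_name = "parent") {
  if (is.character(targets)) {
    tg <- dna_targets()
    idx <- match(targets, tg$name)
    if (anyNA(idx)) stop("unknown DNA target(s): ",
                         paste(targets[is.na(idx)], collapse = ", "))
    targets <- tg[idx, ]
  }
  if (!nrow(targets)) stop("empty target list")
  if (max_chain < 0) stop("max_chain must be >= 0")
  chains <- .chain_multisets(length(steps), max_chain)
  rows <- list()
  for (ms in chains) {
    chain <- steps[ms]
    for (ti in seq_len(nrow(targets))) {
      for (bl in binding_losses) {
        h <- tryCatch(
          adduct_hypothesis(parent, chain, targets[ti, ],
                            binding_loss = if (bl == "none") NULL else bl,
                            parent_name = parent_name),
          error = function(e) NULL)  # impossible chemistry for this parent
        if (!is.null(h)) rows[[length(rows) + 1L]] <- h
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_steps), , drop = FALSE]
  out <- out[!duplicated(out$adduct_formula), , drop = FALSE]
  out <- out[order(out$expected_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hypothesis table to CSV
#'
#' Columns: name, parent_formula, chain, target, binding_loss,
#' adduct_formula, expected_mz (6 d.p.).
#'
#' @param hypotheses Data frame from [enumerate_hypotheses()].
#' @param path Output CSV path.
#' @export
write_hypotheses <- function(hypotheses, path) {
  out <- hypotheses[, c("name", "parent_formula", "chain", "target",
                        "binding_loss", "adduct_formula", "expected_mz")]
  out$expected_mz <- sprintf("%.6f", out$expected_mz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
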