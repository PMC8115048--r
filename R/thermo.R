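#' Denitrification bioenergetics from half-reactions
#'
#' Tools to balance redox half-reactions, couple an electron acceptor to an
#' electron donor, and compute standard Gibbs free energy changes (transformed
#' standard state: pH 7, 25 degrees C) from a table of formation energies.
#' The shipped constants reproduce the stepwise energetics of respiratory
#' denitrification (nitrate -> nitrite -> NO -> N2O -> N2) with pyruvate,
#' fully oxidized to CO2, as the electron donor.
#'
#' @name thermo
NULL

# parse "C3H3O3" style formulas into named element counts
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "" || formula == "0") {
    return(setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.numeric(sub("^[A-Za-z]+", "", parts))
  n[is.na(n)] <- 1
  tapply(n, el, sum)
}

#' Read a formation-energy constants table
#'
#' The table must have columns `species`, `formula`, `charge`, `phase`,
#' `dGf_kJ_per_mol`. Values are transformed standard formation energies
#' (pH 7, 25 degrees C); the proton entry carries the RT*ln(1e-7) term so
#' that reactions can be written with explicit H+.
#'
#' @param path Path to a TSV file; defaults to the constants shipped with the
#'   package.
#' @return A data.frame of species constants.
#' @export
read_thermo_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "denitrification_constants.tsv",
                        package = "amgkit", mustWork = TRUE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "formula", "charge", "phase", "dGf_kJ_per_mol")
  if (!all(need %in% names(tab))) {
    stop("constants table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$species)) stop("duplicate species in constants table")
  if (any(!is.finite(tab$dGf_kJ_per_mol))) stop("non-finite formation energy")
  for (req in c("H2O", "H+")) {
    if (!req %in% tab$species) stop("constants table must contain ", req)
  }
  tab
}

#' Construct a balanced redox half-reaction
#'
#' Half-reactions are written as reductions: `electrons` is the number of
#' electrons consumed. Coefficients are signed (reactants negative, products
#' positive). Mass and charge balance (including the electrons) is checked
#' against the constants table's formulas and charges.
#'
#' @param coef Named numeric vector of signed stoichiometric coefficients.
#' @param electrons Integer number of electrons consumed by the reduction.
#' @param principal Name of the species being reduced (the electron
#'   acceptor of this half-reaction); used when coupling.
#' @param product Name of the reduced product species (used to chain pathway
#'   steps); optional.
#' @param constants Constants table, see [read_thermo_constants()].
#' @return An object of class `half_reaction`.
#' @export
half_reaction <- function(coef, electrons, principal,
                          product = NULL,
                          constants = read_thermo_constants()) {
  stopifnot(is.numeric(coef), !is.null(names(coef)), length(electrons) == 1)
  missing <- setdiff(names(coef), constants$species)
  if (length(missing)) {
    stop("species not in constants table: ", paste(missing, collapse = ", "))
  }
  idx <- match(names(coef), constants$species)
  # element balance
  els <- list()
  for (i in seq_along(coef)) {
    cnt <- parse_formula(constants$formula[idx[i]])
    for (e in names(cnt)) {
      els[[e]] <- (els[[e]] %||% 0) + coef[[i]] * cnt[[e]]
    }
  }
  bad <- names(els)[vapply(els, function(v) abs(v) > 1e-9, logical(1))]
  if (length(bad)) {
    stop("half-reaction not mass-balanced for element(s): ",
         paste(bad, collapse = ", "))
  }
  q <- sum(coef * constants$charge[idx]) + electrons
  if (abs(q) > 1e-9) stop("half-reaction not charge-balanced (residual ", q, ")")
  if (!principal %in% names(coef) || coef[[principal]] >= 0) {
    stop("principal species must appear as a reactant")
  }
  structure(list(coef = coef, electrons = electrons, principal = principal,
                 product = product),
            class = "half_reaction")
}

#' Reverse a half-reaction
#' @param hr A `half_reaction`.
#' @return The same reaction written in the opposite direction.
#' @export
reverse_reaction <- function(hr) {
  stopifnot(inherits(hr, "half_reaction"))
  structure(list(coef = -hr$coef, electrons = -hr$electrons,
                 principal = hr$principal, product = hr$product),
            class = "half_reaction")
}

merge_coef <- function(a, b) {
  sp <- union(names(a), names(b))
  out <- setNames(numeric(length(sp)), sp)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[abs(out) > 1e-12]
}

#' Couple an electron-accepting half-reaction to a donor
#'
#' The donor half-reaction (also written as a reduction) is reversed and
#' scaled so the electrons cancel exactly, then the net reaction is rescaled
#' so the acceptor's principal species has coefficient -1 (per mol of
#' electron acceptor).
#'
#' @param acceptor,donor `half_reaction` objects (both written as reductions).
#' @return A `coupled_reaction`: net signed coefficients, electrons
#'   transferred per mol acceptor, acceptor and product species.
#' @export
couple <- function(acceptor, donor) {
  stopifnot(inherits(acceptor, "half_reaction"), inherits(donor, "half_reaction"))
  if (donor$electrons == 0) stop("donor half-reaction transfers no electrons")
  s <- acceptor$electrons / donor$electrons
  net <- merge_coef(acceptor$coef, -s * donor$coef)
  scale <- -acceptor$coef[[acceptor$principal]]
  structure(list(coef = net / scale,
                 electrons = acceptor$electrons / scale,
                 acceptor = acceptor$principal,
                 product = acceptor$product),
            class = "coupled_reaction")
}

#' Gibbs free energy of a net reaction
#'
#' Computes sum(coefficient x formation energy) over the net reaction,
#' reported per mol of the acceptor species (the coupled reaction is already
#' standardized to acceptor coefficient -1).
#'
#' @param reaction A `coupled_reaction` from [couple()], or any list with
#'   signed `coef`.
#' @param constants Constants table, see [read_thermo_constants()].
#' @return A one-row data.frame: acceptor, electrons, `delta_g_kJ_per_mol`
#'   (per mol acceptor) and `delta_g_per_electron`.
#' @export
delta_g <- function(reaction, constants = read_thermo_constants()) {
  coef <- reaction$coef
  if (length(coef)) {
    idx <- match(names(coef), constants$species)
    if (anyNA(idx)) {
      stop("species missing from constants table: ",
           paste(names(coef)[is.na(idx)], collapse = ", "))
    }
    dg <- sum(coef * constants$dGf_kJ_per_mol[idx])
  } else {
    dg <- 0
  }
  electrons <- reaction$electrons %||% NA_real_
  data.frame(acceptor = reaction$acceptor %||% NA_character_,
             product = reaction$product %||% NA_character_,
             electrons = electrons,
             delta_g_kJ_per_mol = dg,
             delta_g_per_electron = if (!is.na(electrons) && electrons != 0)
               dg / electrons else NA_real_,
             stringsAsFactors = FALSE)
}

#' Sum pathway steps per mol of the initial electron acceptor
#'
#' Steps must chain: the reduced product of each step is the acceptor of the
#' next. Each step's per-mol-acceptor energy is weighted by the moles of that
#' step's acceptor produced per mol of the initial acceptor (so a step that
#' produces half a mol of the next acceptor contributes with weight 1/2).
#'
#' @param steps A data.frame of step results as returned by [delta_g()]
#'   (rows in pathway order, with `acceptor`, `product` and per-acceptor
#'   `product_yield` columns), or a list of such rows.
#' @param product_yield Moles of reduced product species formed per mol of
#'   each step's acceptor (e.g. 0.5 when 2 NO make one N2O).
#' @return Total Gibbs free energy change in kJ per mol of the first
#'   step's acceptor.
#' @export
pathway_sum <- function(steps, product_yield) {
  if (is.list(steps) && !is.data.frame(steps)) steps <- do.call(rbind, steps)
  n <- nrow(steps)
  stopifnot(n >= 1, length(product_yield) == n)
  if (n > 1) {
    chain_ok <- steps$product[-n] == steps$acceptor[-1]
    if (any(!chain_ok, na.rm = TRUE) || anyNA(chain_ok)) {
      stop("pathway steps do not chain: product of one step must be the ",
           "acceptor of the next")
    }
  }
  w <- cumprod(c(1, product_yield[-n]))
  sum(steps$delta_g_kJ_per_mol * w)
}

#' Half-reactions of respiratory denitrification and the pyruvate donor
#'
#' @param constants Constants table used to balance-check the reactions.
#' @return A list with the four acceptor half-reactions (`nar`, `nir`, `nor`,
#'   `nos`), the complete nitrate-to-N2 half-reaction (`complete`), and the
#'   pyruvate/CO2 donor half-reaction (`donor`, written as a reduction;
#'   complete oxidation of pyruvate yields 10 electrons).
#' @export
denitrification_steps <- function(constants = read_thermo_constants()) {
  list(
    nar = half_reaction(c("NO3-" = -1, "H+" = -2, "NO2-" = 1, "H2O" = 1),
                        electrons = 2, principal = "NO3-", product = "NO2-",
                        constants = constants),
    nir = half_reaction(c("NO2-" = -1, "H+" = -2, "NO" = 1, "H2O" = 1),
                        electrons = 1, principal = "NO2-", product = "NO",
                        constants = constants),
    nor = half_reaction(c("NO" = -1, "H+" = -1, "N2O" = 0.5, "H2O" = 0.5),
                        electrons = 1, principal = "NO", product = "N2O",
                        constants = constants),
    nos = half_reaction(c("N2O" = -1, "H+" = -2, "N2" = 1, "H2O" = 1),
                        electrons = 2, principal = "N2O", product = "N2",
                        constants = constants),
    complete = half_reaction(c("NO3-" = -1, "H+" = -6, "N2" = 0.5, "H2O" = 3),
                             electrons = 5, principal = "NO3-", product = "N2",
                             constants = constants),
    donor = half_reaction(c("CO2" = -3, "H+" = -9, "pyruvate" = 1, "H2O" = 3),
                          electrons = 10, principal = "CO2",
                          product = "pyruvate", constants = constants)
  )
}

#' Stepwise and complete denitrification energetics with a pyruvate donor
#'
#' Couples each denitrification step, and the complete nitrate-to-N2
#' reduction, to complete pyruvate oxidation, and reports Gibbs free energy
#' standardized per mol of each step's electron acceptor.
#'
#' @param constants Constants table, see [read_thermo_constants()].
#' @return A data.frame with one row per step (`nar`, `nir`, `nor`, `nos`,
#'   `complete`) and the coupled `delta_g_kJ_per_mol`, plus an attribute
#'   `pathway_sum` holding the Hess-additivity total of the four steps per
#'   mol nitrate.
#' @export
denitrification_energetics <- function(constants = read_thermo_constants()) {
  hr <- denitrification_steps(constants)
  steps <- c("nar", "nir", "nor", "nos", "complete")
  res <- do.call(rbind, lapply(steps, function(s) {
    out <- delta_g(couple(hr[[s]], hr$donor), constants)
    cbind(step = s, out, stringsAsFactors = FALSE)
  }))
  # moles of reduced product per mol acceptor, from the balanced steps
  yields <- vapply(c("nar", "nir", "nor"), function(s) {
    hr[[s]]$coef[[hr[[s]]$product]] / -hr[[s]]$coef[[hr[[s]]$principal]]
  }, numeric(1))
  attr(res, "pathway_sum") <- pathway_sum(res[res$step != "complete", ],
                                          product_yield = c(yields, 1))
  res
}
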