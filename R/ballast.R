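## Core accounting. For one lorica the ballast is
##
##   B = sum_i n_i * w_i  +  sum_j (V_j * c)      [pg]
##
## where n_i are lith counts, w_i per-lith CaCO3 masses (pg), V_j diatom
## particle biovolumes (um^3) and c the biovolume-to-silica conversion
## (pg um^-3). Observations already expressed in pg enter verbatim.

#' Estimate the biomineral ballast of one lorica
#'
#' Converts the particle observations of a single lorica into per-taxon and
#' total CaCO3 and biogenic-silica masses. Coccolith `count` entries
#' contribute `count * lith_mass(taxon)`; `mass_pg` entries contribute
#' verbatim; diatom `biovolume_um3` entries contribute
#' [fragment_silica_mass()] of the biovolume, and diatom `count` entries
#' first expand to biovolume via the reference. Mixed quantity types for the
#' same (taxon, kind) are allowed and summed.
#'
#' @param observations data.frame of observation rows for one lorica (see
#'   [lorica_ledger()]); may be empty.
#' @param reference a [ballast_reference()].
#' @param lorica_id id stored on the result (defaults to the one in
#'   `observations`, or `NA`).
#' @return An object of class `ballast_estimate`: list with `lorica_id`,
#'   `caco3_by_taxon` and `silica_by_taxon` (named numeric, pg),
#'   `caco3_total`, `silica_total`, `total` (pg) and `percent_by_taxon`
#'   (named numeric, unrounded % of total; empty when `total` is 0).
#' @export
#' @examples
#' obs <- data.frame(lorica_id = "L1", particle_taxon = "Emiliania",
#'                   particle_kind = "coccolith", quantity_type = "count",
#'                   quantity = 220)
#' estimate_lorica_ballast(obs)$caco3_total  # 880
estimate_lorica_ballast <- function(observations, reference = ballast_reference(),
                                    lorica_id = NULL) {
  obs <- as.data.frame(observations)
  if (is.null(lorica_id))
    lorica_id <- if (nrow(obs)) as.character(obs$lorica_id[1]) else NA_character_
  if (nrow(obs) && length(unique(obs$lorica_id)) > 1L)
    abort("observations span more than one lorica")

  caco3 <- numeric(0)
  silica <- numeric(0)
  if (nrow(obs)) {
    contrib <- numeric(nrow(obs))
    is_cocc <- obs$particle_kind == "coccolith"
    cc_cnt <- is_cocc & obs$quantity_type == "count"
    cc_pg <- is_cocc & obs$quantity_type == "mass_pg"
    di_cnt <- !is_cocc & obs$quantity_type == "count"
    di_pg <- !is_cocc & obs$quantity_type == "mass_pg"
    di_bv <- !is_cocc & obs$quantity_type == "biovolume_um3"
    if (any(cc_cnt))
      contrib[cc_cnt] <- obs$quantity[cc_cnt] *
        lith_mass(obs$particle_taxon[cc_cnt], reference)
    contrib[cc_pg] <- obs$quantity[cc_pg]
    contrib[di_pg] <- obs$quantity[di_pg]
    if (any(di_bv))
      contrib[di_bv] <- fragment_silica_mass(obs$quantity[di_bv],
                                             reference$constants)
    if (any(di_cnt))
      contrib[di_cnt] <- fragment_silica_mass(
        obs$quantity[di_cnt] *
          diatom_biovolume(obs$particle_taxon[di_cnt],
                           obs$particle_kind[di_cnt], reference),
        reference$constants)
    sum_by <- function(idx) {
      if (!any(idx)) return(numeric(0))
      v <- tapply(contrib[idx], obs$particle_taxon[idx], sum)
      setNames(as.numeric(v), names(v))
    }
    caco3 <- sum_by(is_cocc)
    silica <- sum_by(!is_cocc)
  }
  caco3_total <- sum(caco3)
  silica_total <- sum(silica)
  total <- caco3_total + silica_total
  pct <- if (total > 0) c(caco3, silica) / total * 100 else
    setNames(numeric(0), character(0))
  structure(list(lorica_id = lorica_id,
                 caco3_by_taxon = caco3, silica_by_taxon = silica,
                 caco3_total = caco3_total, silica_total = silica_total,
                 total = total, percent_by_taxon = pct),
            class = "ballast_estimate")
}

#' @export
print.ballast_estimate <- function(x, ...) {
  cat("Ballast estimate for lorica", x$lorica_id, "\n")
  cat("  CaCO3:", round_half_up(x$caco3_total), "pg; silica:",
      round_half_up(x$silica_total, 1), "pg; total:",
      round_half_up(x$total), "pg\n")
  invisible(x)
}

#' Percent composition of a ballast estimate
#'
#' Shares of the total ballast per particle taxon, reported both unrounded
#' and integer-rounded (half away from zero — the display convention used
#' throughout). A zero-total lorica has no defined composition: the function
#' signals a warning and returns an empty table rather than failing.
#'
#' @param estimate a [estimate_lorica_ballast()] result.
#' @return data.frame with columns `particle_taxon`, `kind` (`caco3` /
#'   `silica`), `mass_pg`, `pct` (unrounded), `pct_rounded`; attribute
#'   `undefined` is `TRUE` for a zero-total lorica.
#' @export
percent_composition <- function(estimate) {
  stopifnot(inherits(estimate, "ballast_estimate"))
  taxa <- c(names(estimate$caco3_by_taxon), names(estimate$silica_by_taxon))
  kind <- rep(c("caco3", "silica"),
              c(length(estimate$caco3_by_taxon), length(estimate$silica_by_taxon)))
  mass <- c(estimate$caco3_by_taxon, estimate$silica_by_taxon)
  if (estimate$total <= 0) {
    warning("total ballast is 0; percent composition undefined", call. = FALSE)
    out <- data.frame(particle_taxon = taxa, kind = kind,
                      mass_pg = unname(mass),
                      pct = rep(NA_real_, length(taxa)),
                      pct_rounded = rep(NA_real_, length(taxa)))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  pct <- unname(mass) / estimate$total * 100
  out <- data.frame(particle_taxon = taxa, kind = kind, mass_pg = unname(mass),
                    pct = pct, pct_rounded = round_half_up(pct))
  attr(out, "undefined") <- FALSE
  out
}

#' Dominance classification policy
#'
#' Controls [classify_lorica()]. The heavy-taxon list and the dominance
#' threshold are conventions, not published cutoffs: published groupings name
#' "Calcidiscus-dominated" and "Coccolithus-dominated" types without defining
#' a numeric rule, so both are configurable.
#'
#' @param heavy_taxa coccolith taxa eligible for "<taxon>-dominated" labels.
#' @param threshold minimum mass share of total ballast (default 0.5).
#' @param diatom_cell_first if `TRUE` (default), any whole diatom cell makes
#'   the lorica "diatom-type" before dominance is considered.
#' @return a list of class `dominance_policy`.
#' @export
dominance_policy <- function(heavy_taxa = c("Calcidiscus", "Coccolithus"),
                             threshold = 0.5, diatom_cell_first = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  structure(list(heavy_taxa = heavy_taxa, threshold = threshold,
                 diatom_cell_first = diatom_cell_first),
            class = "dominance_policy")
}

#' Classify a lorica by its dominant ballast
#'
#' Priority rules: (1) any whole diatom cell present -> `"diatom-type"`;
#' (2) a heavy coccolith taxon holding a mass share of total ballast at or
#' above the policy threshold -> `"<taxon>-dominated"`; otherwise (3)
#' `"other"`. Ties on share are broken by heavier per-lith mass, then
#' lexicographically.
#'
#' @param estimate a [estimate_lorica_ballast()] result.
#' @param observations the observation rows of the lorica (needed for the
#'   whole-cell rule); may be `NULL` to skip rule 1.
#' @param policy a [dominance_policy()].
#' @param reference a [ballast_reference()] (tie-break by lith mass).
#' @return list with `label`, `dominant_taxon` (or `NA`), `dominant_share`
#'   (fraction of total ballast held by the largest contributor, 0 for an
#'   empty lorica).
#' @export
classify_lorica <- function(estimate, observations = NULL,
                            policy = dominance_policy(),
                            reference = ballast_reference()) {
  stopifnot(inherits(estimate, "ballast_estimate"))
  shares <- c(estimate$caco3_by_taxon, estimate$silica_by_taxon)
  shares <- if (estimate$total > 0) shares / estimate$total else shares * 0
  dom_taxon <- NA_character_
  dom_share <- 0
  if (length(shares)) {
    ord <- order(-shares,
                 -vapply(names(shares), function(t) {
                   r <- resolve_coccolith(t, reference)
                   if (is.na(r)) 0 else lith_mass(r, reference)
                 }, numeric(1)),
                 names(shares))
    dom_taxon <- names(shares)[ord[1]]
    dom_share <- unname(shares[ord[1]])
  }
  has_cell <- !is.null(observations) && nrow(observations) > 0 &&
    any(observations$particle_kind == "diatom_cell" & observations$quantity > 0)
  label <- if (policy$diatom_cell_first && has_cell) {
    "diatom-type"
  } else {
    heavy <- shares[names(shares) %in% policy$heavy_taxa]
    if (length(heavy) && max(heavy) >= policy$threshold) {
      hv <- heavy[order(-heavy, -lith_mass(names(heavy), reference), names(heavy))]
      paste0(names(hv)[1], "-dominated")
    } else "other"
  }
  list(label = label, dominant_taxon = dom_taxon, dominant_share = dom_share)
}

#' Fit the ballast accounting to a ledger
#'
#' The central function of the package: computes a [estimate_lorica_ballast()]
#' for every lorica in the ledger, classifies each lorica by its dominant
#' ballast, and returns a fitted object with `print`, `summary`, `coef` and
#' `plot` methods. `summary()` produces assemblage summaries (means,
#' population standard deviations, occurrence counts) in the layout of the
#' published tables; `coef()` returns the per-lorica by-taxon mass matrix.
#'
#' @param ledger a [lorica_ledger()] (or a fixture name understood by
#'   [load_fixture()]).
#' @param reference a [ballast_reference()]; defaults to the one attached to
#'   the ledger.
#' @param policy a [dominance_policy()].
#' @return An object of class `ballast`: list with `estimates` (data.frame:
#'   lorica metadata, `caco3_pg`, `silica_pg`, `total_pg`, `label`,
#'   `dominant_taxon`, `dominant_share`), `caco3_by_taxon` and
#'   `silica_by_taxon` (lorica x taxon matrices, pg), `percent_by_taxon`
#'   (lorica x taxon matrix, % of total, 0 rows for zero-total loricae),
#'   `ledger`, `reference`, `policy`, `call`.
#' @seealso [summary.ballast()], [preference_matrix()], [extra_weight_fraction()]
#' @export
#' @examples
#' fit <- ballast(load_fixture("table2"))
#' fit
#' round(coef(fit)[1:3, "Emiliania"])
ballast <- function(ledger, reference = NULL, policy = dominance_policy()) {
  if (is.character(ledger) && length(ledger) == 1L)
    ledger <- load_fixture(ledger)
  stopifnot(inherits(ledger, "lorica_ledger"))
  reference <- reference %||% ledger$reference
  lor <- ledger$loricae
  obs <- ledger$observations
  ests <- lapply(lor$lorica_id, function(id) {
    estimate_lorica_ballast(obs[obs$lorica_id == id, , drop = FALSE],
                            reference, lorica_id = id)
  })
  cls <- lapply(seq_along(ests), function(i) {
    classify_lorica(ests[[i]], obs[obs$lorica_id == lor$lorica_id[i], ,
                                   drop = FALSE],
                    policy, reference)
  })
  estimates <- data.frame(
    lor[c("lorica_id", "tintinnid_taxon", "locality", "region_class",
          "oral_diameter_um", "n_loricae", "group_label", "printed_total_pg")],
    caco3_pg = vapply(ests, `[[`, numeric(1), "caco3_total"),
    silica_pg = vapply(ests, `[[`, numeric(1), "silica_total"),
    total_pg = vapply(ests, `[[`, numeric(1), "total"),
    label = vapply(cls, `[[`, character(1), "label"),
    dominant_taxon = vapply(cls, `[[`, character(1), "dominant_taxon"),
    dominant_share = vapply(cls, `[[`, numeric(1), "dominant_share"),
    row.names = NULL)

  to_matrix <- function(field) {
    taxa <- sort(unique(unlist(lapply(ests, function(e) names(e[[field]])))))
    m <- matrix(0, nrow(lor), length(taxa),
                dimnames = list(lor$lorica_id, taxa))
    for (i in seq_along(ests)) {
      v <- ests[[i]][[field]]
      if (length(v)) m[i, names(v)] <- v
    }
    m
  }
  caco3_m <- to_matrix("caco3_by_taxon")
  silica_m <- to_matrix("silica_by_taxon")
  all_m <- cbind(caco3_m, silica_m)
  pct_m <- all_m / ifelse(estimates$total_pg > 0, estimates$total_pg, Inf) * 100

  structure(list(estimates = estimates, caco3_by_taxon = caco3_m,
                 silica_by_taxon = silica_m, percent_by_taxon = pct_m,
                 ledger = ledger, reference = reference, policy = policy,
                 call = match.call()),
            class = "ballast")
}

#' @export
print.ballast <- function(x, ...) {
  e <- x$estimates
  cat("Lorica ballast fit (", x$ledger$source, "): ",
      nrow(e), " lorica record(s), ", sum(e$n_loricae), " lorica(e)\n", sep = "")
  cat("  total ballast: mean ", round_half_up(mean(e$total_pg)), " pg, range ",
      round_half_up(min(e$total_pg)), "-", round_half_up(max(e$total_pg)),
      " pg\n", sep = "")
  cat("  CaCO3 share of grand total: ",
      round_half_up(100 * sum(e$caco3_pg) / max(sum(e$total_pg), .Machine$double.eps)),
      "%\n", sep = "")
  cat("  labels:", paste(names(table(e$label)), table(e$label),
                         sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Per-lorica by-taxon ballast masses
#'
#' @param object a [ballast()] fit.
#' @param ... ignored.
#' @return matrix (lorica x particle taxon) of masses in pg; coccolith
#'   columns are CaCO3, diatom columns silica.
#' @export
coef.ballast <- function(object, ...) {
  cbind(object$caco3_by_taxon, object$silica_by_taxon)
}

#' Plot per-lorica ballast composition
#'
#' Horizontal stacked bars of CaCO3 and silica ballast per lorica record.
#'
#' @param x a [ballast()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ballast <- function(x, ...) {
  e <- x$estimates
  m <- t(as.matrix(e[, c("caco3_pg", "silica_pg")]))
  colnames(m) <- e$lorica_id
  graphics::barplot(m, horiz = TRUE, las = 1,
                    col = c("grey30", "goldenrod"),
                    xlab = "ballast (pg per lorica)",
                    legend.text = c("CaCO3", "biogenic silica"), ...)
  invisible(x)
}
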