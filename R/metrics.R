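## Derived ecological metrics: how much the agglomerated ballast adds to the
## weight of a bare lorica, how regional assemblages compare, and which
## particle taxa each tintinnid uses (ordered by size, the correlate of prey
## selection).

#' Ballast as a fraction of lorica dry weight
#'
#' Relates a per-lorica ballast mass to the literature dry weight of a bare
#' lorica (default 40 000 +/- 20 000 pg). The dry-weight uncertainty is
#' propagated into an interval: `lower = ballast / (W + sd)`,
#' `upper = ballast / (W - sd)`.
#'
#' @param ballast_total numeric vector of per-lorica ballast totals (pg).
#' @param constants the `constants` element of a [ballast_reference()].
#' @return data.frame with columns `ballast_pg`, `fraction`, `percent`,
#'   `lower_percent`, `upper_percent`.
#' @export
#' @examples
#' extra_weight_fraction(10540)$percent  # 26.35 -> "an extra ~25%"
extra_weight_fraction <- function(ballast_total,
                                  constants = ballast_reference()$constants) {
  if (any(ballast_total < 0)) abort("ballast_total must be non-negative")
  W <- constants$lorica_dry_weight_pg
  s <- constants$lorica_dry_weight_sd_pg
  frac <- ballast_total / W
  data.frame(ballast_pg = ballast_total,
             fraction = frac,
             percent = 100 * frac,
             lower_percent = 100 * ballast_total / (W + s),
             upper_percent = if (W - s > 0) 100 * ballast_total / (W - s) else Inf)
}

#' Ratio of two group mean ballast loads
#'
#' @param mean_a,mean_b group mean total ballast (pg), either numbers or
#'   single-group [summarize_assemblage()] objects (their `total_mean_pg` is
#'   used). `mean_b` must be positive.
#' @return list with `ratio` (= a / b), `numerator`, `denominator`.
#' @export
#' @examples
#' regional_ratio(19922, 2428)$ratio  # 8.2: cold-water loricae ~8x heavier
regional_ratio <- function(mean_a, mean_b) {
  pick <- function(x) {
    if (inherits(x, "assemblage_summary")) {
      if (nrow(x$groups) != 1L)
        abort("summary passed to regional_ratio must have exactly one group")
      x$groups$total_mean_pg
    } else as.numeric(x)
  }
  a <- pick(mean_a)
  b <- pick(mean_b)
  if (b <= 0) abort("denominator group mean must be positive")
  list(ratio = a / b, numerator = a, denominator = b)
}

## characteristic size (um) used for ordering particle columns: coccoliths by
## lith size (alias-resolved), diatoms by their particle size; NA if unknown
particle_size_key <- function(taxon, kind, reference) {
  if (kind == "caco3" || kind == "coccolith") {
    res <- resolve_coccolith(taxon, reference)
    if (is.na(res)) return(NA_real_)
    row <- reference$coccoliths[reference$coccoliths$taxon == res, ]
    mean(c(row$size_min_um, row$size_max_um), na.rm = TRUE)
  } else {
    row <- reference$diatoms[reference$diatoms$taxon == taxon, ]
    if (!nrow(row)) return(NA_real_)
    mean(row$size_um, na.rm = TRUE)
  }
}

#' Taxon preference matrix
#'
#' Cross-tabulates tintinnid taxa against the particle taxa found on their
#' loricae. Rows are ordered by increasing lorica oral diameter, coccolith
#' columns by increasing lith size, with diatom particles as a trailing
#' column block ordered by particle size — the ordering that exposes the
#' size-matching of particle use to tintinnid size. Cells hold the occurrence
#' fraction (loricae carrying the taxon / loricae examined; occurrence
#' annotations override computed indicators) and the mean mass share of total
#' ballast. Taxa without a size key are placed last with a warning.
#'
#' @param ledgers a [lorica_ledger()], [ballast()] fit, or a list of either.
#' @param reference a [ballast_reference()]; default: from the first ledger.
#' @return An object of class `preference_matrix`: list with matrices
#'   `occurrence` (fraction), `occ_x`, `occ_n`, `mass_share` (mean fraction
#'   of total ballast), and the ordered keys `tintinnids` (taxon,
#'   oral_diameter_um, n) and `particles` (taxon, kind, size_um).
#' @export
#' @examples
#' pm <- preference_matrix(list(load_fixture("table2"), load_fixture("table5")))
#' pm$occ_x["Codonellopsis cf. soyai", "Emiliania"]  # 9 (of 11)
preference_matrix <- function(ledgers, reference = NULL) {
  if (!is.list(ledgers) || inherits(ledgers, c("lorica_ledger", "ballast")))
    ledgers <- list(ledgers)
  fits <- lapply(ledgers, function(l) if (inherits(l, "ballast")) l else ballast(l))
  reference <- reference %||% fits[[1]]$reference

  ## row key: tintinnid taxa by mean oral diameter
  meta <- do.call(rbind, lapply(fits, function(f)
    f$estimates[c("tintinnid_taxon", "oral_diameter_um", "n_loricae")]))
  tint <- do.call(rbind, lapply(split(meta, meta$tintinnid_taxon), function(d)
    data.frame(taxon = d$tintinnid_taxon[1],
               oral_diameter_um = w_mean(ifelse(is.na(d$oral_diameter_um), NA,
                                                d$oral_diameter_um),
                                         d$n_loricae),
               n = sum(d$n_loricae))))
  if (anyNA(tint$oral_diameter_um))
    warning("tintinnid taxa without oral diameter placed last: ",
            paste(tint$taxon[is.na(tint$oral_diameter_um)], collapse = ", "),
            call. = FALSE)
  tint <- tint[order(is.na(tint$oral_diameter_um), tint$oral_diameter_um,
                     tint$taxon), ]

  ## column key: particle taxa by size, coccoliths first
  cols <- unique(do.call(rbind, lapply(fits, function(f) {
    kind <- rep(c("coccolith", "diatom"),
                c(ncol(f$caco3_by_taxon), ncol(f$silica_by_taxon)))
    occ <- f$ledger$occurrences
    rbind(data.frame(taxon = colnames(coef(f)), kind = kind),
          if (nrow(occ)) data.frame(
            taxon = occ$particle_taxon,
            kind = ifelse(occ$particle_kind == "coccolith",
                          "coccolith", "diatom")))
  })))
  cols$size_um <- mapply(particle_size_key, cols$taxon, cols$kind,
                         MoreArgs = list(reference = reference))
  if (anyNA(cols$size_um))
    warning("particle taxa without size key placed last: ",
            paste(cols$taxon[is.na(cols$size_um)], collapse = ", "),
            call. = FALSE)
  cols <- cols[order(cols$kind != "coccolith", is.na(cols$size_um),
                     cols$size_um, cols$taxon), ]

  occ_x <- occ_n <- share_w <- share_sum <-
    matrix(0, nrow(tint), nrow(cols),
           dimnames = list(tint$taxon, cols$taxon))
  for (f in fits) {
    e <- f$estimates
    M <- coef(f)
    P <- f$percent_by_taxon
    occ <- f$ledger$occurrences
    all_ids <- e$lorica_id
    ds_ann <- occ[!occ$lorica_id %in% all_ids, , drop = FALSE]
    lo_ann <- occ[occ$lorica_id %in% all_ids, , drop = FALSE]
    for (tt in unique(e$tintinnid_taxon)) {
      idx <- which(e$tintinnid_taxon == tt)
      w <- e$n_loricae[idx]
      ids <- e$lorica_id[idx]
      occ_n[tt, ] <- occ_n[tt, ] + sum(w)
      for (tx in colnames(occ_x)) {
        if (nrow(ds_ann) && tx %in% ds_ann$particle_taxon &&
            setequal(ids, all_ids)) {
          x <- sum(ds_ann$x[ds_ann$particle_taxon == tx])
        } else {
          ann <- lo_ann[lo_ann$particle_taxon == tx & lo_ann$lorica_id %in% ids, ,
                        drop = FALSE]
          covered <- ids %in% ann$lorica_id
          pos <- if (tx %in% colnames(M)) M[idx[!covered], tx] > 0 else
            logical(sum(!covered))
          x <- sum(ann$x) + sum(w[!covered] * pos)
        }
        occ_x[tt, tx] <- occ_x[tt, tx] + x
        if (tx %in% colnames(P)) {
          share_sum[tt, tx] <- share_sum[tt, tx] + sum(w * P[idx, tx] / 100)
        }
        share_w[tt, tx] <- share_w[tt, tx] + sum(w)
      }
    }
  }
  structure(list(occurrence = occ_x / occ_n, occ_x = occ_x, occ_n = occ_n,
                 mass_share = share_sum / share_w,
                 tintinnids = tint, particles = cols),
            class = "preference_matrix")
}

#' @export
print.preference_matrix <- function(x, digits = 2, ...) {
  cat("Taxon preference matrix (occurrence fraction)\n")
  cat("rows: tintinnids by increasing oral diameter;",
      "cols: particles by increasing size\n")
  print(round(x$occurrence, digits))
  invisible(x)
}

#' Bubble plot of a preference matrix
#'
#' Circle area scales with the occurrence fraction; filled circles mark taxa
#' that on average contribute at least `share_cut` of total ballast.
#'
#' @param x a [preference_matrix()].
#' @param share_cut mass-share threshold for filled circles (default 0.25).
#' @param ... ignored.
#' @export
plot.preference_matrix <- function(x, share_cut = 0.25, ...) {
  nr <- nrow(x$occurrence)
  nc <- ncol(x$occurrence)
  op <- par(mar = c(1, 10, 8, 1))
  on.exit(par(op))
  plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(nr + 0.5, 0.5),
       axes = FALSE, xlab = "", ylab = "")
  axis(3, at = seq_len(nc), labels = colnames(x$occurrence), las = 2,
       cex.axis = 0.8, tick = FALSE)
  axis(2, at = seq_len(nr), labels = rownames(x$occurrence), las = 1,
       cex.axis = 0.8, tick = FALSE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    f <- x$occurrence[i, j]
    if (is.finite(f) && f > 0) {
      filled <- is.finite(x$mass_share[i, j]) && x$mass_share[i, j] >= share_cut
      points(j, i, cex = 0.4 + 3 * sqrt(f), pch = 21,
             bg = if (filled) adjustcolor("steelblue", 0.8) else "white")
    }
  }
  invisible(x)
}
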