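## Assemblage summaries mirror the layout of the published tables: per-taxon
## mean +/- population sd (divisor n, the only convention consistent with the
## printed values), occurrence "x of n", and group totals. A taxon absent
## from a lorica counts as 0 pg in means, not as missing. Group-mean
## pseudo-loricae (n_loricae > 1) contribute with weight n_loricae; their
## within-group variance is unrecoverable, so sds over pseudo-loricae reflect
## between-group spread only.

w_mean <- function(x, w) sum(w * x) / sum(w)
w_pop_sd <- function(x, w) {
  m <- w_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Summarise an assemblage of ballast estimates
#'
#' Groups loricae (default: by tintinnid taxon and locality) and computes,
#' per particle taxon: arithmetic mean and population standard deviation of
#' the per-lorica mass (absent taxa contribute 0), mean/sd of the percent
#' share of total ballast, and the occurrence count "x of n" (loricae with a
#' strictly positive quantity; group-level occurrence annotations override
#' the computed indicator where present). Group totals (mean +/- population
#' sd of per-lorica total ballast) are reported alongside.
#'
#' @param object a [ballast()] fit or a [lorica_ledger()].
#' @param group_by character vector of grouping columns from the lorica
#'   metadata (subset of `tintinnid_taxon`, `locality`, `region_class`,
#'   `group_label`).
#' @param ... passed to [ballast()] when `object` is a ledger.
#' @return An object of class `assemblage_summary`: list with `groups`
#'   (data.frame: group, n, total_mean_pg, total_sd_pg, caco3_mean_pg,
#'   silica_mean_pg), `taxa` (data.frame: group, particle_taxon, kind,
#'   mean_pg, sd_pg, pct_mean, pct_sd, occ_x, occ_n, occurrence_only) and
#'   `group_by`.
#' @export
#' @examples
#' s <- summarize_assemblage(ballast(load_fixture("table2")))
#' subset(s$taxa, particle_taxon == "Emiliania")[, c("mean_pg", "sd_pg")]
summarize_assemblage <- function(object,
                                 group_by = c("tintinnid_taxon", "locality"),
                                 ...) {
  fit <- if (inherits(object, "ballast")) object else ballast(object, ...)
  e <- fit$estimates
  bad <- setdiff(group_by, names(e))
  if (length(bad)) abort("unknown grouping column(s): ", paste(bad, collapse = ", "))
  M <- coef(fit)
  kind <- rep(c("caco3", "silica"),
              c(ncol(fit$caco3_by_taxon), ncol(fit$silica_by_taxon)))
  names(kind) <- colnames(M)
  P <- fit$percent_by_taxon
  occ <- fit$ledger$occurrences
  all_ids <- fit$ledger$loricae$lorica_id
  dataset_scope <- occ[!occ$lorica_id %in% all_ids, , drop = FALSE]
  lorica_scope <- occ[occ$lorica_id %in% all_ids, , drop = FALSE]

  key <- interaction(e[group_by], drop = TRUE, sep = " / ")
  groups_df <- NULL
  taxa_df <- NULL
  for (g in levels(key)) {
    idx <- which(key == g)
    if (!length(idx)) next
    w <- e$n_loricae[idx]
    n <- sum(w)
    ids <- e$lorica_id[idx]
    groups_df <- rbind(groups_df, data.frame(
      group = g, n = n,
      total_mean_pg = w_mean(e$total_pg[idx], w),
      total_sd_pg = w_pop_sd(e$total_pg[idx], w),
      caco3_mean_pg = w_mean(e$caco3_pg[idx], w),
      silica_mean_pg = w_mean(e$silica_pg[idx], w)))

    whole_dataset <- setequal(ids, all_ids)
    taxa_here <- colnames(M)[colSums(M[idx, , drop = FALSE]) > 0]
    ann_taxa <- unique(c(
      lorica_scope$particle_taxon[lorica_scope$lorica_id %in% ids],
      if (whole_dataset) dataset_scope$particle_taxon))
    for (tx in union(taxa_here, ann_taxa)) {
      measured <- tx %in% colnames(M)
      ds_ann <- dataset_scope[dataset_scope$particle_taxon == tx, , drop = FALSE]
      if (whole_dataset && nrow(ds_ann)) {
        x <- sum(ds_ann$x)
      } else {
        ann <- lorica_scope[lorica_scope$particle_taxon == tx &
                              lorica_scope$lorica_id %in% ids, , drop = FALSE]
        covered <- ids %in% ann$lorica_id
        pos <- if (measured) M[idx[!covered], tx] > 0 else
          rep(FALSE, sum(!covered))
        x <- sum(ann$x) + sum(w[!covered] * pos)
      }
      taxa_df <- rbind(taxa_df, data.frame(
        group = g, particle_taxon = tx,
        kind = if (measured) unname(kind[tx]) else
          ifelse(any(c(lorica_scope$particle_kind[lorica_scope$particle_taxon == tx],
                       dataset_scope$particle_kind[dataset_scope$particle_taxon == tx])
                     == "coccolith"), "caco3", "silica"),
        mean_pg = if (measured) w_mean(M[idx, tx], w) else NA_real_,
        sd_pg = if (measured) w_pop_sd(M[idx, tx], w) else NA_real_,
        pct_mean = if (measured) w_mean(P[idx, tx], w) else NA_real_,
        pct_sd = if (measured) w_pop_sd(P[idx, tx], w) else NA_real_,
        occ_x = as.integer(x), occ_n = as.integer(n),
        occurrence_only = !measured))
    }
  }
  structure(list(groups = groups_df, taxa = taxa_df, group_by = group_by),
            class = "assemblage_summary")
}

#' Assemblage summary of a ballast fit
#'
#' @param object a [ballast()] fit.
#' @param group_by see [summarize_assemblage()].
#' @param ... ignored.
#' @return an `assemblage_summary`; see [summarize_assemblage()].
#' @export
summary.ballast <- function(object, group_by = c("tintinnid_taxon", "locality"),
                            ...) {
  summarize_assemblage(object, group_by = group_by)
}

#' @export
print.assemblage_summary <- function(x, ...) {
  fmt <- function(m, s) paste0(round_half_up(m), " ± ", round_half_up(s))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(g$group, " (n = ", g$n, "): total ", fmt(g$total_mean_pg, g$total_sd_pg),
        " pg/lorica\n", sep = "")
    tx <- x$taxa[x$taxa$group == g$group, ]
    tx <- tx[order(tx$kind, -ifelse(is.na(tx$mean_pg), -1, tx$mean_pg)), ]
    for (j in seq_len(nrow(tx))) {
      t <- tx[j, ]
      cell <- if (t$occurrence_only || is.na(t$mean_pg))
        paste(t$occ_x, "of", t$occ_n)
      else paste0(fmt(t$mean_pg, t$sd_pg), " pg (", round_half_up(t$pct_mean),
                  " ± ", round_half_up(t$pct_sd), "%), ",
                  t$occ_x, " of ", t$occ_n)
      cat("  ", format(t$particle_taxon, width = 26), cell, "\n")
    }
  }
  invisible(x)
}
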