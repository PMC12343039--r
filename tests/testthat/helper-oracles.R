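# Independent oracles, deliberately written without touching the package's
# accounting path: plain loops over observation rows with the published
# constants restated literally.

ORACLE_LITH_PG <- c(Emiliania = 4, Gladiolithus = 4, Syracosphaera = 10,
                    Umbilicosphaera = 16, Florisphaera = 20, Rhabdosphaera = 60,
                    Calcidiscus = 124, Helicosphaera = 140, Coccolithus = 152,
                    # aliases by morphology
                    Gephyrocapsa = 4, Alisphaera = 4, Coronosphaera = 10)
ORACLE_SI_PG_PER_UM3 <- 0.0005 * 28

# brute-force per-lorica masses: list(caco3 = named vec, silica = named vec)
oracle_lorica_masses <- function(obs_rows) {
  caco3 <- c()
  silica <- c()
  add <- function(tab, tx, v) {
    tab[tx] <- (if (tx %in% names(tab)) tab[[tx]] else 0) + v
    tab
  }
  for (i in seq_len(nrow(obs_rows))) {
    r <- obs_rows[i, ]
    if (r$particle_kind == "coccolith") {
      v <- if (r$quantity_type == "count")
        r$quantity * ORACLE_LITH_PG[[r$particle_taxon]] else r$quantity
      caco3 <- add(caco3, r$particle_taxon, v)
    } else {
      v <- if (r$quantity_type == "mass_pg") r$quantity
      else if (r$quantity_type == "biovolume_um3") r$quantity * ORACLE_SI_PG_PER_UM3
      else stop("oracle: diatom counts not supported")
      silica <- add(silica, r$particle_taxon, v)
    }
  }
  list(caco3 = caco3, silica = silica,
       total = sum(caco3) + sum(silica))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-pass population sd
oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

# tiny deterministic ledger used by several unit tests
toy_ledger <- function() {
  lorica_ledger(
    loricae = data.frame(
      lorica_id = c("A", "B"),
      tintinnid_taxon = "Toyella toyi",
      locality = "Toy Sea", region_class = "temperate",
      oral_diameter_um = 20),
    observations = data.frame(
      lorica_id = c("A", "A", "B"),
      particle_taxon = c("Emiliania", "Coscinodiscus", "Calcidiscus"),
      particle_kind = c("coccolith", "diatom_fragment", "coccolith"),
      quantity_type = c("count", "biovolume_um3", "count"),
      quantity = c(10, 375, 2)))
}
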