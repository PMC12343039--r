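## Per-lorica particle ledgers.
##
## A ledger couples two tables: one row per lorica (metadata), and one row per
## counted/measured particle class on a lorica. Quantities are polymorphic:
## `count` (integer particles), `mass_pg` (pre-converted mass, as printed in
## literature tables), or `biovolume_um3` (geometric volume, converted to
## silica downstream). Group-level occurrence annotations ("x of n") that
## cannot be assigned to individual loricae are carried in a third table.

LORICA_COLS <- c("lorica_id", "tintinnid_taxon", "locality", "region_class",
                 "oral_diameter_um", "bowl_length_um", "n_loricae",
                 "group_label", "printed_total_pg")
OBS_COLS <- c("lorica_id", "particle_taxon", "particle_kind",
              "quantity_type", "quantity")
OCC_COLS <- c("lorica_id", "particle_taxon", "particle_kind", "x", "n")

PARTICLE_KINDS <- c("coccolith", "diatom_fragment", "diatom_cell")
QUANTITY_TYPES <- c("count", "mass_pg", "biovolume_um3")
REGION_CLASSES <- c("tropical", "temperate", "polar")

#' Construct a per-lorica particle ledger
#'
#' Couples lorica metadata with particle observations and validates the pair:
#' unique lorica ids, referential integrity, non-negative quantities, integer
#' counts, legal kind/quantity-type combinations (coccoliths may be `count` or
#' `mass_pg`; diatom particles additionally `biovolume_um3`), and — for any
#' coccolith entered as a `count` — a per-lith mass resolvable through the
#' reference (directly or by alias). Validation errors name the offending row.
#'
#' @param loricae data.frame with columns `lorica_id`, `tintinnid_taxon`,
#'   `locality`, `region_class`; optional `oral_diameter_um`, `bowl_length_um`,
#'   `n_loricae` (>= 1, default 1; > 1 marks a group-mean pseudo-lorica
#'   encoding a printed summary row), `group_label`, `printed_total_pg`.
#' @param observations data.frame with columns `lorica_id`, `particle_taxon`,
#'   `particle_kind` (coccolith / diatom_fragment / diatom_cell),
#'   `quantity_type` (count / mass_pg / biovolume_um3), `quantity`.
#' @param reference a [ballast_reference()] used to resolve taxa.
#' @param occurrences optional data.frame of group-level occurrence
#'   annotations: `lorica_id`, `particle_taxon`, `particle_kind`, `x`, `n`.
#' @param source free-text provenance label.
#' @return An object of class `lorica_ledger`.
#' @export
lorica_ledger <- function(loricae, observations, reference = ballast_reference(),
                          occurrences = NULL, source = "user") {
  loricae <- as.data.frame(loricae)
  observations <- as.data.frame(observations)
  if (is.null(loricae$oral_diameter_um)) loricae$oral_diameter_um <- NA_real_
  if (is.null(loricae$bowl_length_um)) loricae$bowl_length_um <- NA_real_
  if (is.null(loricae$n_loricae)) loricae$n_loricae <- 1L
  if (is.null(loricae$group_label)) loricae$group_label <- NA_character_
  if (is.null(loricae$printed_total_pg)) loricae$printed_total_pg <- NA_real_
  loricae <- loricae[LORICA_COLS]
  ## canonical column types so CSV round-trips are value-identical
  for (col in c("lorica_id", "tintinnid_taxon", "locality", "region_class",
                "group_label"))
    loricae[[col]] <- as.character(loricae[[col]])
  for (col in c("oral_diameter_um", "bowl_length_um", "printed_total_pg"))
    loricae[[col]] <- as.numeric(loricae[[col]])
  loricae$n_loricae <- as.integer(loricae$n_loricae)
  if (nrow(observations) == 0L) {
    observations <- data.frame(lorica_id = character(), particle_taxon = character(),
                               particle_kind = character(), quantity_type = character(),
                               quantity = numeric())
  }
  observations <- observations[OBS_COLS]
  if (is.null(occurrences)) {
    occurrences <- data.frame(lorica_id = character(), particle_taxon = character(),
                              particle_kind = character(), x = integer(), n = integer())
  }
  occurrences <- as.data.frame(occurrences)[OCC_COLS]
  x <- structure(list(loricae = loricae, observations = observations,
                      occurrences = occurrences, reference = reference,
                      source = source),
                 class = "lorica_ledger")
  validate_ledger(x)
  x
}

#' Validate a lorica ledger
#'
#' Called by every constructor/reader; exported so users can re-validate after
#' manual edits. Errors report the first offending row number of the relevant
#' table.
#'
#' @param ledger a `lorica_ledger`.
#' @return the ledger, invisibly, or an error.
#' @export
validate_ledger <- function(ledger) {
  lor <- ledger$loricae
  obs <- ledger$observations
  row_err <- function(tab, i, ...) abort(tab, " row ", i, ": ", ...)

  dup <- which(duplicated(lor$lorica_id))
  if (length(dup)) row_err("loricae", dup[1], "duplicate lorica_id ",
                           sq(lor$lorica_id[dup[1]]))
  bad <- which(!lor$region_class %in% REGION_CLASSES)
  if (length(bad)) row_err("loricae", bad[1], "region_class must be one of ",
                           paste(REGION_CLASSES, collapse = "/"))
  for (col in c("oral_diameter_um", "bowl_length_um")) {
    bad <- which(!is.na(lor[[col]]) & lor[[col]] <= 0)
    if (length(bad)) row_err("loricae", bad[1], col, " must be positive")
  }
  bad <- which(is.na(lor$n_loricae) | lor$n_loricae < 1)
  if (length(bad)) row_err("loricae", bad[1], "n_loricae must be >= 1")

  if (nrow(obs)) {
    bad <- which(!obs$lorica_id %in% lor$lorica_id)
    if (length(bad)) row_err("observations", bad[1], "unknown lorica_id ",
                             sq(obs$lorica_id[bad[1]]))
    bad <- which(!obs$particle_kind %in% PARTICLE_KINDS)
    if (length(bad)) row_err("observations", bad[1], "invalid particle_kind ",
                             sq(obs$particle_kind[bad[1]]))
    bad <- which(!obs$quantity_type %in% QUANTITY_TYPES)
    if (length(bad)) row_err("observations", bad[1], "invalid quantity_type ",
                             sq(obs$quantity_type[bad[1]]))
    bad <- which(is.na(obs$quantity) | obs$quantity < 0)
    if (length(bad)) row_err("observations", bad[1], "quantity must be non-negative")
    bad <- which(obs$quantity_type == "count" &
                   abs(obs$quantity - round(obs$quantity)) > 1e-9)
    if (length(bad)) row_err("observations", bad[1], "count quantity must be integer")
    bad <- which(obs$particle_kind == "coccolith" &
                   obs$quantity_type == "biovolume_um3")
    if (length(bad)) row_err("observations", bad[1],
                             "coccoliths take quantity_type count or mass_pg")
    ## count-entered particles need a reference mass/biovolume to be usable
    cc <- which(obs$particle_kind == "coccolith" & obs$quantity_type == "count")
    if (length(cc)) {
      res <- resolve_coccolith(obs$particle_taxon[cc], ledger$reference)
      if (anyNA(res)) {
        i <- cc[which(is.na(res))[1]]
        row_err("observations", i, "coccolith taxon ", sq(obs$particle_taxon[i]),
                " has no lith mass or alias in the reference")
      }
    }
    dd <- which(obs$particle_kind != "coccolith" & obs$quantity_type == "count")
    if (length(dd)) {
      ok <- tryCatch({
        diatom_biovolume(obs$particle_taxon[dd], obs$particle_kind[dd],
                         ledger$reference)
        TRUE
      }, error = function(e) e)
      if (!isTRUE(ok)) row_err("observations", dd[1], conditionMessage(ok))
    }
  }
  occ <- ledger$occurrences
  if (nrow(occ)) {
    bad <- which(occ$x < 0 | occ$n < 1 | occ$x > occ$n)
    if (length(bad)) row_err("occurrences", bad[1], "need 0 <= x <= n, n >= 1")
  }
  invisible(ledger)
}

#' Read a ledger from CSV files
#'
#' `path` may be a directory holding `loricae.csv` and `observations.csv`
#' (plus optional `occurrences.csv`), or a single CSV with a `record_type`
#' column (`lorica` / `observation` / `occurrence` rows, union of columns).
#' Files are UTF-8, comma-separated, with a header row; lines beginning `#`
#' are provenance comments and are skipped.
#'
#' @param path directory or single-file CSV path.
#' @param reference a [ballast_reference()].
#' @return a validated [lorica_ledger()].
#' @export
read_ledger <- function(path, reference = ballast_reference()) {
  rd <- function(f) read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
  if (dir.exists(path)) {
    lf <- file.path(path, "loricae.csv")
    of <- file.path(path, "observations.csv")
    for (f in c(lf, of)) if (!file.exists(f)) abort("missing file: ", f)
    lor <- rd(lf)
    obs <- rd(of)
    ocf <- file.path(path, "occurrences.csv")
    occ <- if (file.exists(ocf)) rd(ocf) else NULL
  } else if (file.exists(path)) {
    all <- rd(path)
    if (is.null(all$record_type))
      abort("single-file ledgers need a record_type column")
    lor <- all[all$record_type == "lorica", setdiff(names(all), "record_type")]
    obs <- all[all$record_type == "observation", ]
    occ <- all[all$record_type == "occurrence", ]
    occ <- if (nrow(occ)) occ else NULL
  } else abort("ledger path not found: ", path)
  if (nrow(obs)) obs$quantity <- as.numeric(obs$quantity)
  lorica_ledger(lor, obs, reference = reference, occurrences = occ,
                source = path)
}

#' Write a ledger to CSV files
#'
#' Writes `loricae.csv`, `observations.csv` and (when annotations exist)
#' `occurrences.csv` into `path`. Round-trip identity holds:
#' `read_ledger(write_ledger(x, d))` reproduces all values.
#'
#' @param ledger a `lorica_ledger`.
#' @param path output directory (created if needed).
#' @param header optional character vector of provenance comment lines
#'   (written with a leading `# `).
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path, header = NULL) {
  stopifnot(inherits(ledger, "lorica_ledger"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    con <- file(file.path(path, f), "w", encoding = "UTF-8")
    on.exit(close(con))
    if (length(header)) writeLines(paste("#", header), con)
    write.csv(df, con, row.names = FALSE, quote = TRUE)
  }
  wr(ledger$loricae, "loricae.csv")
  wr(ledger$observations, "observations.csv")
  if (nrow(ledger$occurrences)) wr(ledger$occurrences, "occurrences.csv")
  invisible(path)
}

#' @export
print.lorica_ledger <- function(x, ...) {
  n_eff <- sum(x$loricae$n_loricae)
  cat("Lorica particle ledger (", x$source, ")\n", sep = "")
  cat("  loricae: ", nrow(x$loricae), " record(s) representing ", n_eff,
      " lorica(e); taxa: ",
      paste(unique(x$loricae$tintinnid_taxon), collapse = ", "), "\n", sep = "")
  cat("  observations:", nrow(x$observations), "particle classes;",
      "occurrence annotations:", nrow(x$occurrences), "\n")
  invisible(x)
}
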