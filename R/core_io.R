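# Domain types and CSV readers/writers for the pipeline.
#
# Conventions used throughout:
#   * one "plant" record = one pot (pots carry three seedlings but replicates
#     are reported per pot);
#   * days are integer days-after-treatment (DAT), day 0 = stress imposition;
#   * 1 g of water is taken as 1 ml.

pg_stop <- function(kind, ...) {
  msg <- paste0(...)
  stop(structure(class = c(paste0("pg_", kind, "_error"), "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_cols <- function(df, cols, what, path = NULL) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    pg_stop("schema", what, if (!is.null(path)) paste0(" '", path, "'"),
            ": missing required column(s): ", paste(miss, collapse = ", "))
  }
}

check_finite_numeric <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))
      pg_stop("parse", what, ": column '", cl, "' is not numeric",
              if (length(bad)) paste0(" (first bad row: ", bad[1], ")"))
    }
    nf <- which(!is.finite(v) & !is.na(v))
    if (length(nf)) {
      pg_stop("parse", what, ": non-finite value in column '", cl,
              "', row ", nf[1])
    }
  }
}

#' Experiment design
#'
#' Describes the layout of a pot experiment: genotypes crossed with two water
#' treatments (`well_watered`, `water_stressed`), each cell replicated as
#' whole pots. One plant record corresponds to one pot.
#'
#' @param plants data.frame with columns `plant_id`, `genotype`, `treatment`,
#'   `replicate`.
#' @param days ordered integer vector of observation days (DAT).
#' @return an object of class `pg_design`: the validated plants data.frame
#'   with attributes `genotypes`, `treatments`, `days`.
#' @export
pg_design <- function(plants, days) {
  check_cols(plants, c("plant_id", "genotype", "treatment", "replicate"),
             "design")
  plants$plant_id <- as.character(plants$plant_id)
  plants$genotype <- as.character(plants$genotype)
  plants$treatment <- as.character(plants$treatment)
  plants$replicate <- as.integer(plants$replicate)
  ok_treat <- c("well_watered", "water_stressed")
  bad <- setdiff(unique(plants$treatment), ok_treat)
  if (length(bad)) {
    pg_stop("schema", "design: unknown treatment level(s): ",
            paste(bad, collapse = ", "), " (expected ",
            paste(ok_treat, collapse = "/"), ")")
  }
  if (anyDuplicated(plants$plant_id)) {
    pg_stop("integrity", "design: duplicated plant_id: ",
            plants$plant_id[duplicated(plants$plant_id)][1])
  }
  if (any(plants$replicate < 1L)) pg_stop("range", "design: replicate < 1")
  days <- as.integer(days)
  if (length(days) < 2L || any(diff(days) <= 0L)) {
    pg_stop("schema", "design: days must be >= 2 strictly increasing integers")
  }
  if (length(unique(plants$genotype)) < 2L) {
    pg_stop("schema", "design: need >= 2 genotypes")
  }
  structure(plants, class = c("pg_design", "data.frame"),
            genotypes = sort(unique(plants$genotype)),
            treatments = ok_treat, days = days)
}

#' @export
print.pg_design <- function(x, ...) {
  cat("<pg_design> ", length(attr(x, "genotypes")), " genotypes x ",
      length(unique(x$treatment)), " treatment(s), ", nrow(x), " pots, days ",
      min(attr(x, "days")), "..", max(attr(x, "days")), " DAT\n", sep = "")
  invisible(x)
}

#' Feature table
#'
#' Per plant-day rows of image-derived predictors. Key columns `plant_id`,
#' `day`; all other columns must be registered `<feature>.<view>` names
#' (see [pg_feature_registry()]). `NA` marks a missing observation (e.g. an
#' empty segmentation mask); all present values must be finite.
#'
#' @param df data.frame with `plant_id`, `day` and feature columns.
#' @param check_registry reject unregistered feature column names.
#' @return object of class `pg_features` (a data.frame).
#' @export
pg_features <- function(df, check_registry = TRUE) {
  check_cols(df, c("plant_id", "day"), "feature table")
  df$plant_id <- as.character(df$plant_id)
  df$day <- as.integer(df$day)
  key <- paste(df$plant_id, df$day, sep = "@")
  if (anyDuplicated(key)) {
    pg_stop("integrity", "feature table: duplicate (plant_id, day): ",
            key[duplicated(key)][1])
  }
  feat_cols <- setdiff(names(df), c("plant_id", "day"))
  if (!length(feat_cols)) pg_stop("schema", "feature table: no feature columns")
  if (check_registry) {
    bad <- setdiff(feat_cols, pg_feature_columns())
    if (length(bad)) {
      pg_stop("schema", "feature table: unregistered feature column(s): ",
              paste(bad, collapse = ", "))
    }
  }
  check_finite_numeric(df, feat_cols, "feature table")
  structure(as.data.frame(df), class = c("pg_features", "data.frame"))
}

#' Geometry-only predictor block of a feature table
#'
#' @param features a `pg_features` table.
#' @return data.frame restricted to `plant_id`, `day` and the registered
#'   geometric columns present (NIR columns dropped).
#' @export
geometry_columns <- function(features) {
  keep <- intersect(pg_feature_columns(geometry_only = TRUE), names(features))
  features[, c("plant_id", "day", keep), drop = FALSE]
}

#' Harvested biomass table
#'
#' @param df data.frame with `plant_id`, `fresh_weight_g`, `dry_weight_g`,
#'   `harvest_day`.
#' @return object of class `pg_biomass`.
#' @export
pg_biomass <- function(df) {
  check_cols(df, c("plant_id", "fresh_weight_g", "dry_weight_g", "harvest_day"),
             "biomass table")
  df$plant_id <- as.character(df$plant_id)
  check_finite_numeric(df, c("fresh_weight_g", "dry_weight_g"), "biomass table")
  if (anyDuplicated(df$plant_id)) {
    pg_stop("integrity", "biomass table: duplicated plant_id")
  }
  if (any(df$dry_weight_g < 0)) pg_stop("range", "biomass table: dry weight < 0")
  if (any(df$fresh_weight_g < df$dry_weight_g)) {
    pg_stop("range", "biomass table: fresh weight < dry weight (row ",
            which(df$fresh_weight_g < df$dry_weight_g)[1], ")")
  }
  structure(as.data.frame(df), class = c("pg_biomass", "data.frame"))
}

#' Watering ledger
#'
#' Daily pre/post-watering pot weights. Water added must equal the weight
#' delta (1 g = 1 ml) within `tol` grams.
#'
#' @param df data.frame with `pot_id`, `day`, `weight_before_g`,
#'   `weight_after_g`, `water_added_ml`.
#' @param pot_constants optional data.frame with `pot_id`, `tare_g`,
#'   `dry_soil_g` used for %-field-capacity bookkeeping.
#' @param tol tolerance (g) for the water-added consistency check.
#' @return object of class `pg_ledger`.
#' @export
pg_ledger <- function(df, pot_constants = NULL, tol = 2) {
  check_cols(df, c("pot_id", "day", "weight_before_g", "weight_after_g",
                   "water_added_ml"), "watering ledger")
  df$pot_id <- as.character(df$pot_id)
  df$day <- as.integer(df$day)
  num <- c("weight_before_g", "weight_after_g", "water_added_ml")
  check_finite_numeric(df, num, "watering ledger")
  if (any(df$weight_before_g < 0)) pg_stop("range", "ledger: negative weight")
  bad <- which(df$weight_after_g < df$weight_before_g - tol)
  if (length(bad)) {
    pg_stop("range", "ledger: weight_after < weight_before at row ", bad[1])
  }
  delta <- df$weight_after_g - df$weight_before_g
  off <- which(abs(delta - df$water_added_ml) > tol)
  if (length(off)) {
    pg_stop("integrity", "ledger: water_added_ml inconsistent with weight ",
            "delta at row ", off[1], " (delta ", round(delta[off[1]], 1),
            " g vs recorded ", df$water_added_ml[off[1]], " ml)")
  }
  df <- df[order(df$pot_id, df$day), ]
  rownames(df) <- NULL
  structure(df, class = c("pg_ledger", "data.frame"),
            pot_constants = pot_constants)
}

# ---- readers / writers ------------------------------------------------------

#' Read pipeline CSV inputs
#'
#' Readers for the four tabular inputs. All files are UTF-8 comma-separated
#' with a header row; schemas:
#' \itemize{
#'   \item design.csv: `plant_id,genotype,treatment,replicate`
#'   \item features.csv: `plant_id,day,<feature>.<view>...`
#'   \item watering.csv: `pot_id,day,weight_before_g,weight_after_g,water_added_ml`
#'     (optionally `tare_g,dry_soil_g`)
#'   \item biomass.csv: `plant_id,fresh_weight_g,dry_weight_g,harvest_day`
#' }
#' Files violating a type invariant are rejected with a located error.
#'
#' @param path CSV file path.
#' @param days for `read_design`: observation days (DAT); defaults to a
#'   `days` column if present in the file.
#' @param design optional `pg_design` used to cross-check that ledger pot ids
#'   and biomass plant ids are known.
#' @return the validated object (`pg_features`, `pg_ledger`, `pg_biomass`,
#'   `pg_design`).
#' @name readers
NULL

read_csv_strict <- function(path) {
  if (!file.exists(path)) pg_stop("io", "file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readers
#' @export
read_feature_table <- function(path) {
  pg_features(read_csv_strict(path))
}

#' @rdname readers
#' @export
write_feature_table <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname readers
#' @export
read_watering_ledger <- function(path, design = NULL) {
  df <- read_csv_strict(path)
  pc <- NULL
  if (all(c("tare_g", "dry_soil_g") %in% names(df))) {
    pc <- unique(df[, c("pot_id", "tare_g", "dry_soil_g")])
    df <- df[, setdiff(names(df), c("tare_g", "dry_soil_g"))]
  }
  led <- pg_ledger(df, pot_constants = pc)
  if (!is.null(design)) {
    orphan <- setdiff(unique(led$pot_id), design$plant_id)
    if (length(orphan)) {
      pg_stop("referential", "ledger: pot_id not in design: ",
              paste(head(orphan, 3), collapse = ", "))
    }
  }
  led
}

#' @rdname readers
#' @export
read_biomass_table <- function(path, design = NULL) {
  bm <- pg_biomass(read_csv_strict(path))
  if (!is.null(design)) {
    orphan <- setdiff(bm$plant_id, design$plant_id)
    if (length(orphan)) {
      pg_stop("referential", "biomass: plant_id not in design: ",
              paste(head(orphan, 3), collapse = ", "))
    }
  }
  bm
}

#' @rdname readers
#' @export
read_design <- function(path, days = NULL) {
  df <- read_csv_strict(path)
  if (is.null(days)) {
    if ("day" %in% names(df)) {
      days <- sort(unique(as.integer(df$day)))
      df <- unique(df[, setdiff(names(df), "day")])
    } else {
      pg_stop("schema", "design '", path,
              "': supply `days` or include a day column")
    }
  }
  pg_design(df, days)
}
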