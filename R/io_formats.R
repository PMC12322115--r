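# Tabular readers/writers and run configuration.
#
# Conventions: all tables are TSV with mandatory headers, decimal point, no
# thousands separators. Gene identity is by case-sensitive symbol string.
# Timepoints are positive integers ordered by acquisition.

VARIANT_COLS <- c("patient_id", "sample_id", "timepoint", "gene",
                  "protein_change", "ref_count", "alt_count")

#' Validate a variant table
#'
#' Checks the seven mandatory columns, integer read counts, positive
#' coverage, and uniqueness of (sample_id, gene, protein_change). Adds a
#' `vaf` column (`alt_count / (alt_count + ref_count)`).
#'
#' @param df data.frame with columns `patient_id`, `sample_id`, `timepoint`,
#'   `gene`, `protein_change`, `ref_count`, `alt_count`.
#' @return The validated data.frame, with `timepoint` coerced to integer and
#'   a `vaf` column, classed `lp_variant_table`.
#' @export
variant_table <- function(df) {
  missing_cols <- setdiff(VARIANT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("ref_count", "alt_count", "timepoint")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != as.integer(v))) {
      bad <- which(!is.numeric(v) | !is.finite(v) | v != suppressWarnings(as.integer(v)))
      stop("column '", col, "' must be integer; first bad row: ",
           if (length(bad)) bad[1] else NA)
    }
    df[[col]] <- as.integer(v)
  }
  if (any(df$timepoint < 1L)) {
    stop("timepoint must be >= 1; first bad row: ", which(df$timepoint < 1L)[1])
  }
  if (any(df$ref_count < 0L) || any(df$alt_count < 0L)) {
    stop("read counts must be >= 0")
  }
  zero <- df$ref_count + df$alt_count == 0L
  if (any(zero)) {
    stop("row ", which(zero)[1], " has zero total read count (ref + alt = 0)")
  }
  key <- paste(df$sample_id, df$gene, df$protein_change, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, gene, protein_change) key at row ",
         which(duplicated(key))[1])
  }
  df$vaf <- df$alt_count / (df$alt_count + df$ref_count)
  class(df) <- c("lp_variant_table", "data.frame")
  df
}

#' Read a longitudinal variant table from TSV
#'
#' @param path path to a TSV file with header columns `patient_id`,
#'   `sample_id`, `timepoint`, `gene`, `protein_change`, `ref_count`,
#'   `alt_count`.
#' @return A validated variant table (see [variant_table]).
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  variant_table(df)
}

#' Write a variant table to TSV
#' @param x variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x[, VARIANT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (set name -> genes); the
#'   description is kept in attribute `"description"` of each set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(structure(list(), class = "lp_gene_sets"))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT line ", i, ": empty gene set")
    nms[i] <- parts[1]
    sets[[i]] <- structure(genes, description = parts[2])
  }
  if (anyDuplicated(nms)) {
    stop("duplicated gene-set name: ", nms[which(duplicated(nms))[1]])
  }
  names(sets) <- nms
  structure(sets, class = "lp_gene_sets")
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a numeric matrix from TSV (first column = row names)
#'
#' Used for expression matrices (genes x samples) and drug AUC matrices
#' (samples x drugs).
#'
#' @param path path to TSV; first column holds row identifiers, remaining
#'   header fields are column identifiers.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  rn <- as.character(df[[1]])
  if (anyDuplicated(rn)) stop("duplicate row identifier: ",
                              rn[which(duplicated(rn))[1]])
  if (anyDuplicated(names(df)[-1])) stop("duplicate column identifier")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix file ", path)
  if (any(!is.finite(m))) stop("non-finite values in matrix file ", path)
  rownames(m) <- rn
  m
}

#' Write a numeric matrix to TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header for the row-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' A single global seed plus documented thresholds for every stage. All
#' stochastic stages derive child seeds deterministically from `seed`.
#'
#' @param seed integer global seed.
#' @param ... named overrides of the defaults.
#' @return A named list classed `lp_config`.
#' @export
lp_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed      = as.integer(seed),
    presence  = list(min_alt = 3L, min_vaf = 0.02),
    pharmaco  = list(p_cut = 0.1, lfc_cut = 0.2, method = "paired_t"),
    signature = list(top_k = 100L),
    gsea      = list(n_perm = 1000L, weight = 1),
    ssgsea    = list(alpha = 0.25),
    qc        = list(mito_max = 0.30, feat_min = 200L, feat_max = 6000L),
    survival  = list(horizon_months = 60),
    synergy   = list(ci_fa = NA_real_)  # NA: CI at the achieved combo effect
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  p <- cfg$presence
  if (p$min_alt < 1 || p$min_vaf < 0 || p$min_vaf >= 1) {
    stop("presence rule out of range: min_alt >= 1, 0 <= min_vaf < 1")
  }
  if (cfg$pharmaco$p_cut <= 0 || cfg$pharmaco$p_cut > 1) {
    stop("p_cut must be in (0, 1]")
  }
  if (cfg$pharmaco$lfc_cut < 0) stop("lfc_cut must be >= 0")
  if (cfg$signature$top_k < 1) stop("top_k must be >= 1")
  q <- cfg$qc
  if (q$mito_max <= 0 || q$mito_max >= 1) stop("mito_max must be in (0, 1)")
  if (q$feat_min <= 0 || q$feat_min >= q$feat_max) {
    stop("feature-count bounds must satisfy 0 < feat_min < feat_max")
  }
  if (cfg$survival$horizon_months <= 0) stop("horizon must be positive")
  class(cfg) <- "lp_config"
  cfg
}

#' Read / write run configuration (YAML)
#' @param path YAML file path.
#' @return [read_config()] returns a validated `lp_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg configuration list from [lp_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Derive a child seed for a named stage
#'
#' Deterministic map from (global seed, stage name) to a 32-bit-safe child
#' seed, so stages are reproducible independently of execution order.
#'
#' @param seed integer global seed.
#' @param stage stage name.
#' @return integer child seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Write a JSON provenance record for a run
#'
#' Records the configuration, its hash, the seed and the package version —
#' enough to reproduce the run.
#'
#' @param path output JSON path.
#' @param cfg configuration (`lp_config`).
#' @param stage stage name being run.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, cfg, stage) {
  cfg_str <- yaml::as.yaml(unclass(cfg))
  rec <- list(
    stage = stage,
    seed = cfg$seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        (seq_along(utf8ToInt(cfg_str)) %% 97 + 1)) %% 4294967296),
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("longipharm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Minimal leveled logger
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... message parts, pasted together.
#' @return the formatted line, invisibly.
#' @export
lp_log <- function(level = c("INFO", "DEBUG", "WARN", "ERROR"), ...) {
  level <- match.arg(level)
  threshold <- getOption("longipharm.loglevel", "INFO")
  ranks <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  line <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = ""))
  if (ranks[level] >= ranks[threshold]) message(line)
  invisible(line)
}
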