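#' @importFrom stats aov anova cor dhyper qnorm quantile rbinom rexp rlnorm
#'   rmultinom rnorm rpois runif sd setNames pt p.adjust
#' @importFrom utils combn head read.table write.table
NULL

COUNT_TABLE_HEADER <- "#phycobycatch count-table v1"

#' Validate a sample-by-feature count matrix
#'
#' Count tables are plain integer matrices with samples as rows and features
#' as columns; row and column names are the sample and feature identifiers.
#'
#' @param counts numeric matrix with unique `rownames` (samples) and
#'   `colnames` (features); every cell a non-negative integer.
#' @return The matrix, invisibly, after validation.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort_fmt("count table must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_fmt("count table must carry sample (row) and feature (column) names")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    abort_fmt("duplicate sample id: %s", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    abort_fmt("duplicate feature id: %s", paste(dup, collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    abort_fmt(
      "invalid count %s at (sample '%s', feature '%s'): must be a non-negative integer",
      format(counts[bad[1L]]), rownames(counts)[i[1L]], colnames(counts)[i[2L]])
  }
  invisible(counts)
}

#' Read a count table from TSV
#'
#' Expects a tab-separated file whose header row carries feature ids and whose
#' first column carries sample ids; leading `#` comment lines are ignored.
#' Malformed input is rejected with the offending coordinate, never coerced.
#'
#' @param path path to a TSV file.
#' @return integer matrix, samples x features.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) abort_fmt("%s: empty count table", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  feature_ids <- header[-1L]
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    abort_fmt("%s: duplicate feature id: %s", path, paste(dup, collapse = ", "))
  body <- fields[-1L]
  sample_ids <- vapply(body, `[`, "", 1L)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    abort_fmt("%s: duplicate sample id: %s", path, paste(dup, collapse = ", "))
  mat <- matrix(0L, length(body), length(feature_ids),
                dimnames = list(sample_ids, feature_ids))
  for (r in seq_along(body)) {
    row <- body[[r]]
    if (length(row) != length(header))
      abort_fmt("%s: row for sample '%s' has %d fields, expected %d",
                path, sample_ids[r], length(row), length(header))
    vals <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad))
      abort_fmt("%s: invalid count '%s' at (sample '%s', feature '%s')",
                path, row[-1L][bad[1L]], sample_ids[r], feature_ids[bad[1L]])
    mat[r, ] <- as.integer(vals)
  }
  validate_count_table(mat)
  mat
}

#' Write a count table to TSV
#'
#' @param counts validated count matrix (samples x features).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  con <- file(path, "wb")  # binary mode: newline-terminated, byte-stable
  on.exit(close(con))
  writeLines(c(
    COUNT_TABLE_HEADER,
    paste(c("sample_id", colnames(counts)), collapse = "\t"),
    vapply(seq_len(nrow(counts)), function(r) {
      paste(c(rownames(counts)[r], format(counts[r, ], scientific = FALSE, trim = TRUE)),
            collapse = "\t")
    }, "")
  ), con, sep = "\n")
  invisible(path)
}

#' Parse a 96-well label
#'
#' Labels are parsed case-insensitively and normalized to an upper-case row
#' letter plus an unpadded column number ("a01" is well "A1").
#'
#' @param well character vector of well labels.
#' @return data.frame with columns `well` (normalized label), `row` (1-8),
#'   `col` (1-12).
#' @export
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Ha-h])0*([1-9][0-9]?)$", well))
  bad <- lengths(m) != 3L
  row <- ifelse(bad, NA_integer_,
                match(toupper(vapply(m, function(x) x[2L] %||% "", "")), LETTERS[1:8]))
  col <- suppressWarnings(as.integer(vapply(m, function(x) x[3L] %||% "", "")))
  if (anyNA(row) || anyNA(col) || any(col > 12L))
    abort_fmt("well label outside the A1..H12 grid: %s",
              paste(unique(well[is.na(row) | is.na(col) | col > 12L]), collapse = ", "))
  data.frame(well = paste0(LETTERS[row], col), row = row, col = col,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Read a plate layout from CSV
#'
#' @param path CSV with columns `sample_id` and `well`.
#' @return data.frame with columns `sample_id`, `well`, `row`, `col`; one row
#'   per sample, one sample per well.
#' @export
read_plate_layout <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "well") %in% names(df)))
    abort_fmt("%s: plate layout needs columns sample_id, well", path)
  plate_layout(df$sample_id, df$well)
}

#' Construct a plate layout
#'
#' @param sample_id character vector of sample ids.
#' @param well parallel vector of well labels within A1..H12.
#' @return data.frame with columns `sample_id`, `well`, `row`, `col`.
#' @export
plate_layout <- function(sample_id, well) {
  if (length(sample_id) != length(well))
    abort_fmt("sample_id and well must have equal length")
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) abort_fmt("duplicate sample id: %s", paste(dup, collapse = ", "))
  pw <- parse_well(well)
  dup <- unique(pw$well[duplicated(pw$well)])
  if (length(dup))
    abort_fmt("more than one sample assigned to well %s", paste(dup, collapse = ", "))
  data.frame(sample_id = as.character(sample_id), pw, stringsAsFactors = FALSE)
}

#' Write a plate layout to CSV
#' @param layout plate layout data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("sample_id,well",
               paste(layout$sample_id, layout$well, sep = ",")), con, sep = "\n")
  invisible(path)
}

#' Read a rooted phylogeny of features from newick
#'
#' Tips without a branch length are assigned length 0 with a warning.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort_fmt("%s: newick parse error: %s",
                                                 path, conditionMessage(e)))
  if (is.null(tree)) abort_fmt("%s: newick parse error", path)
  if (is.null(tree$edge.length)) {
    warning(sprintf("%s: tree has no branch lengths; defaulting all to 0", path))
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning(sprintf("%s: missing branch lengths defaulted to 0", path))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    abort_fmt("%s: negative branch lengths", path)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    abort_fmt("%s: duplicate tip label: %s", path, paste(dup, collapse = ", "))
  tree
}

#' Construct a feature taxonomy table
#'
#' @param feature_id feature ids.
#' @param kingdom,phylum,class,order,family,genus rank labels ("" if unknown).
#' @param host_set genus labels flagged as the cyanobacterial host
#'   (default Prochlorococcus and Synechococcus).
#' @param organelle_set lineage labels flagged as organelle-derived
#'   (default mitochondria and chloroplast, matched case-insensitively at any
#'   rank).
#' @return data.frame with the six rank columns plus logical `is_host` and
#'   `is_organelle`.
#' @export
taxonomy_table <- function(feature_id, kingdom = "", phylum = "", class = "",
                           order = "", family = "", genus = "",
                           host_set = c("Prochlorococcus", "Synechococcus"),
                           organelle_set = c("mitochondria", "chloroplast")) {
  n <- length(feature_id)
  dup <- unique(feature_id[duplicated(feature_id)])
  if (length(dup)) abort_fmt("duplicate feature id: %s", paste(dup, collapse = ", "))
  df <- data.frame(feature_id = as.character(feature_id),
                   kingdom = rep_len(kingdom, n), phylum = rep_len(phylum, n),
                   class = rep_len(class, n), order = rep_len(order, n),
                   family = rep_len(family, n), genus = rep_len(genus, n),
                   stringsAsFactors = FALSE)
  ranks <- df[, c("kingdom", "phylum", "class", "order", "family", "genus")]
  df$is_host <- df$genus %in% host_set
  df$is_organelle <- apply(ranks, 1L, function(x)
    any(tolower(x) %in% tolower(organelle_set)))
  df
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with columns `feature_id` and any of the six rank columns.
#' @inheritParams taxonomy_table
#' @return taxonomy data.frame with `is_host`/`is_organelle` flags recomputed
#'   from the configured sets.
#' @export
read_taxonomy <- function(path,
                          host_set = c("Prochlorococcus", "Synechococcus"),
                          organelle_set = c("mitochondria", "chloroplast")) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = character())
  if (!"feature_id" %in% names(df))
    abort_fmt("%s: taxonomy needs a feature_id column", path)
  get <- function(r) if (r %in% names(df)) df[[r]] else ""
  taxonomy_table(df$feature_id, get("kingdom"), get("phylum"), get("class"),
                 get("order"), get("family"), get("genus"),
                 host_set = host_set, organelle_set = organelle_set)
}

#' Read per-sample culture metadata from TSV
#'
#' Missing values are encoded as the literal string `NA`.
#'
#' @param path TSV with a `sample_id` column plus metadata columns
#'   (host_genus, clade, ecotype, cruise, isolation_method, depth_m, latitude,
#'   longitude, isolation_year).
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  if (!"sample_id" %in% names(df))
    abort_fmt("%s: metadata needs a sample_id column", path)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) abort_fmt("%s: duplicate sample id: %s", path,
                             paste(dup, collapse = ", "))
  if ("depth_m" %in% names(df) && any(df$depth_m < 0, na.rm = TRUE))
    abort_fmt("%s: negative depth_m", path)
  if ("isolation_year" %in% names(df)) {
    yr <- df$isolation_year
    if (any(!is.na(yr) & (yr < 1800 | yr > 2200)))
      abort_fmt("%s: isolation_year outside plausible calendar range", path)
  }
  df
}

#' Default analysis configuration
#'
#' Every threshold used by the pipeline, with the study defaults: 10%
#' adjacency ratio, 0.2% abundance floor, 8-neighbour adjacency, 97% OTU
#' identity, 1000 permutations.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    adjacency_ratio = 0.10,
    abundance_floor = 0.002,
    adjacency_scheme = "edge8",
    identity_threshold = 0.97,
    n_permutations = 1000L,
    host_set = c("Prochlorococcus", "Synechococcus"),
    organelle_set = c("mitochondria", "chloroplast"),
    cut_cosmopolitan = 0.75,
    cut_sparse = 0.25,
    depth_cut_m = 200,
    seed = 1L
  )
}

#' Read a JSON configuration, filling unset keys with defaults
#'
#' @param path JSON file of configuration overrides, or `NULL` for defaults.
#' @return named list of parameters.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      abort_fmt("%s: unknown config keys: %s", path, paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}
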