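#' @importFrom stats chisq.test cor cutree dist hclust lm na.omit p.adjust
#'   pchisq prcomp predict pt qt quantile rbinom rlnorm rnorm rpois runif sd
#'   t.test var coef
#' @importFrom utils read.delim write.table packageVersion
NULL

HABITATS <- c("freshwater", "saltwater", "outgroup")

`%||%` <- function(a, b) if (is.null(a)) b else a

sa_log <- function(..., .envir = parent.frame()) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [saltadapt] ", ...)
  message(msg)
  invisible(msg)
}

#' Derive a reproducible substream seed from a root seed
#'
#' Each named stage gets its own deterministic seed so that adding one
#' generator or stage call never perturbs the random stream of another.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name (e.g. "pam", "expression", "ml").
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  offsets <- c(
    pam = 101L, expression = 211L, metabolites = 307L, featured = 401L,
    ml = 503L, coexpress = 601L, integrate = 701L, pipeline = 809L,
    bootstrap = 907L, permute = 1009L
  )
  off <- offsets[[stage]] %||% (sum(utf8ToInt(stage)) %% 1024L)
  s <- (abs(as.numeric(root_seed)) * 2654435.0 + as.numeric(off) * 40503.0) %%
    2147483646
  as.integer(s) + 1L
}

## ---- species metadata -------------------------------------------------

#' Construct and validate species metadata
#'
#' @param species_id character vector of unique species identifiers.
#' @param habitat character vector, each one of `"freshwater"`,
#'   `"saltwater"` or `"outgroup"`.
#' @param display_name optional display names.
#' @return a `species_metadata` data frame.
#' @export
species_metadata <- function(species_id, habitat, display_name = NULL) {
  species_id <- as.character(species_id)
  habitat <- as.character(habitat)
  if (anyDuplicated(species_id))
    stop("duplicate species_id: ",
         paste(unique(species_id[duplicated(species_id)]), collapse = ", "))
  bad <- setdiff(unique(habitat), HABITATS)
  if (length(bad))
    stop("unknown habitat value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(HABITATS, collapse = ", "))
  if (length(habitat) != length(species_id))
    stop("species_id and habitat lengths differ")
  df <- data.frame(species_id = species_id, habitat = habitat,
                   display_name = display_name %||% species_id,
                   stringsAsFactors = FALSE)
  class(df) <- c("species_metadata", "data.frame")
  df
}

#' Read species metadata from a TSV file
#'
#' Expects columns `species_id` and `habitat` (optionally `display_name`).
#'
#' @param path file path.
#' @return a `species_metadata` data frame.
#' @export
read_species_metadata <- function(path) {
  df <- read_tsv_checked(path, required = c("species_id", "habitat"))
  species_metadata(df$species_id, df$habitat, df$display_name)
}

#' @export
write_species_metadata <- function(meta, path) {
  write_tsv(as.data.frame(meta), path)
}

## ---- orthogroup counts ------------------------------------------------

#' Construct an orthogroup gene-count table
#'
#' @param counts integer matrix, one row per orthogroup (family), one column
#'   per species; nonnegative gene copy counts.
#' @return an `orthogroup_counts` object.
#' @export
orthogroup_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have family row names and species column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate family id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts))) stop("duplicate species id")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts), class = "orthogroup_counts")
}

#' Read an orthogroup gene-count table
#'
#' Parses the OrthoFinder `Orthogroups.GeneCount.tsv` dialect: a header row,
#' first column the orthogroup id, one integer column per species, and an
#' optional trailing `Total` column (dropped with a log note).
#'
#' @param path file path.
#' @return an `orthogroup_counts` object.
#' @export
read_orthogroup_counts <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expected at least one species column in ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate family id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tab <- df[, -1L, drop = FALSE]
  if (tolower(colnames(tab)[ncol(tab)]) == "total") {
    tab <- tab[, -ncol(tab), drop = FALSE]
    sa_log("dropped trailing 'Total' column from ", path)
  }
  m <- matrix(NA_integer_, nrow(tab), ncol(tab),
              dimnames = list(ids, colnames(tab)))
  for (j in seq_len(ncol(tab))) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      stop(sprintf("non-integer count at (row %d, col %d) value '%s' in %s",
                   bad[1L], j + 1L, tab[bad[1L], j], path))
    m[, j] <- as.integer(v)
  }
  orthogroup_counts(m)
}

#' @export
write_orthogroup_counts <- function(oc, path) {
  df <- data.frame(Orthogroup = rownames(oc$counts), oc$counts,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Binarize orthogroup counts into a presence-absence matrix
#'
#' Entry is 1 iff the species has at least one gene copy in the family.
#' Output orientation is species x families; all-zero families are retained.
#'
#' @param counts an `orthogroup_counts` object (or a `presence_absence_matrix`,
#'   returned unchanged: binarization is idempotent).
#' @return a `presence_absence_matrix` object.
#' @export
to_presence_absence <- function(counts) {
  if (inherits(counts, "presence_absence_matrix")) {
    counts$values[] <- as.integer(counts$values > 0)
    return(counts)
  }
  stopifnot(inherits(counts, "orthogroup_counts"))
  v <- t(counts$counts > 0L)
  storage.mode(v) <- "integer"
  structure(list(values = v), class = "presence_absence_matrix")
}

#' @export
presence_absence_matrix <- function(values) {
  values <- as.matrix(values)
  if (!all(values %in% c(0L, 1L))) stop("presence-absence values must be 0/1")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("species row names and family column names required")
  storage.mode(values) <- "integer"
  structure(list(values = values), class = "presence_absence_matrix")
}

#' @export
print.orthogroup_counts <- function(x, ...) {
  cat(sprintf("orthogroup_counts: %d families x %d species\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat(sprintf("presence_absence_matrix: %d species x %d families (density %.3f)\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

## ---- expression, traits, gene map -------------------------------------

#' Construct an expression matrix (genes x samples, FPKM-like units)
#'
#' @param values nonnegative numeric matrix, genes in rows, samples in
#'   columns.
#' @param species_tag species identifier for the whole matrix.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, species_tag) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene row names and sample column names required")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  structure(list(values = values, species_tag = as.character(species_tag)),
            class = "expression_matrix")
}

#' Read an expression matrix from TSV (first column gene id)
#' @param path file path.
#' @param species_tag species identifier for the matrix.
#' @export
read_expression <- function(path, species_tag) {
  df <- read_tsv_checked(path, required = NULL)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  expression_matrix(m, species_tag)
}

#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Construct and validate a sample trait table
#'
#' Traits follow the stress-experiment encoding: `severity` is the salinity
#' of the treatment (g/L), `duration` the treatment duration (hours),
#' `damage` is 1 when the alga is away from its preferred salinity, and
#' `mem25_specific` is 1 for samples of the focal euryhaline species.
#'
#' @param df data frame with columns sample_id, severity, duration, damage,
#'   mem25_specific.
#' @return a `sample_traits` data frame.
#' @export
sample_traits <- function(df) {
  req <- c("sample_id", "severity", "duration", "damage", "mem25_specific")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing trait column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in traits")
  for (b in c("damage", "mem25_specific"))
    if (!all(df[[b]] %in% c(0, 1)))
      stop("trait '", b, "' must be binary 0/1")
  if (any(df$severity < 0)) stop("severity must be >= 0")
  df <- df[, req]
  rownames(df) <- NULL
  class(df) <- c("sample_traits", "data.frame")
  df
}

#' Read a sample trait table from TSV
#' @param path file path.
#' @export
read_traits <- function(path) {
  sample_traits(read_tsv_checked(
    path, required = c("sample_id", "severity", "duration", "damage",
                       "mem25_specific"),
    numeric_cols = c("severity", "duration", "damage", "mem25_specific")))
}

#' @export
write_traits <- function(tr, path) write_tsv(as.data.frame(tr), path)

#' Construct a gene-to-orthogroup membership map
#' @param df data frame with columns gene_id, species_id, orthogroup_id.
#' @export
gene_map <- function(df) {
  req <- c("gene_id", "species_id", "orthogroup_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing gene map column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("a gene must map to exactly one orthogroup; duplicated gene_id")
  df <- df[, req]
  rownames(df) <- NULL
  class(df) <- c("gene_map", "data.frame")
  df
}

#' Read a gene-to-orthogroup map from TSV
#' @param path file path.
#' @export
read_gene_map <- function(path) {
  gene_map(read_tsv_checked(
    path, required = c("gene_id", "species_id", "orthogroup_id")))
}

#' @export
write_gene_map <- function(gm, path) write_tsv(as.data.frame(gm), path)

## ---- metabolites -------------------------------------------------------

#' Construct a metabolite abundance matrix
#'
#' @param values positive numeric matrix, metabolites x samples.
#' @param condition character vector of condition labels, one per sample.
#' @return a `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(values, condition) {
  values <- as.matrix(values)
  if (any(values <= 0)) stop("metabolite abundances must be > 0")
  if (length(condition) != ncol(values))
    stop("one condition label per sample required")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("metabolite row names and sample column names required")
  tab <- table(condition)
  if (any(tab < 2)) stop("at least 2 replicates per condition required")
  structure(list(values = values, condition = as.character(condition)),
            class = "metabolite_matrix")
}

#' Read a metabolite table from TSV
#'
#' First column metabolite id; remaining columns samples. Condition labels
#' are taken from a `condition` row in `traits_path` style files or supplied
#' directly.
#'
#' @param path file path.
#' @param condition character vector of per-sample condition labels, or a
#'   path to a two-column TSV (sample_id, condition).
#' @export
read_metabolites <- function(path, condition) {
  df <- read_tsv_checked(path, required = NULL)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (length(condition) == 1L && file.exists(condition)) {
    cd <- read_tsv_checked(condition, required = c("sample_id", "condition"))
    condition <- cd$condition[match(colnames(m), cd$sample_id)]
    if (anyNA(condition)) stop("condition missing for some samples")
  }
  metabolite_matrix(m, condition)
}

#' @export
write_metabolites <- function(mm, path, condition_path = NULL) {
  df <- data.frame(metabolite_id = rownames(mm$values), mm$values,
                   check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(condition_path))
    write_tsv(data.frame(sample_id = colnames(mm$values),
                         condition = mm$condition), condition_path)
  invisible(path)
}

## ---- analysis config ---------------------------------------------------

#' Analysis configuration with the study's default thresholds
#'
#' Defaults encode the pipeline's published operating points: featured-family
#' presence cutoff 0.6, 5-fold CV with feature batches of 50, soft-threshold
#' grid with scale-free fit R^2 > 0.9, module-trait rule |r| >= 0.75 and
#' p <= 0.005 with minimum module size 30, transcript-metabolite rule
#' PCC > 0.90 and PCCP < 0.001, and the metabolite differential-abundance
#' rule |log2FC| >= 1 with p <= 0.05.
#'
#' @param ... named overrides of any default field.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    cutoff = 0.6,
    cv_folds = 5L,
    batch_size = 50L,
    soft_power_grid = c(1:10, 12L, 14L, 16L, 18L, 20L),
    scale_free_r2_min = 0.9,
    module_min_size = 30L,
    module_cut_height = 0.99,
    module_trait_r_min = 0.75,
    module_trait_p_max = 0.005,
    pcc_min = 0.90,
    pccp_max = 0.001,
    da_log2fc_min = 1.0,
    da_p_max = 0.05,
    bootstrap_reps = 200L,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$cutoff <= 0.5 || cfg$cutoff > 1) stop("cutoff must be in (0.5, 1]")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  for (f in c("module_trait_p_max", "pccp_max", "da_p_max"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$pcc_min < -1 || cfg$pcc_min > 1) stop("pcc_min must be in [-1, 1]")
  if (is.null(cfg$seed)) stop("seed is mandatory")
  invisible(cfg)
}

#' Read a key:value configuration file (YAML subset)
#' @param path file path.
#' @param ... named overrides applied after the file values.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  ov <- list(...)
  vals[names(ov)] <- ov
  do.call(analysis_config, vals)
}

## ---- low-level TSV helpers ---------------------------------------------

read_tsv_checked <- function(path, required, numeric_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop("missing required column(s) in ", path, ": ",
           paste(miss, collapse = ", "))
  }
  for (nc in intersect(numeric_cols, names(df))) df[[nc]] <- as.numeric(df[[nc]])
  df
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
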