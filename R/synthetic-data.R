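# Seeded generator of gene-expression-like datasets with planted structure.
# Emulates the regime of the small-n / large-p microarray panels used to
# evaluate wrapper gene selection (tens to hundreds of samples, thousands of
# features, 2-26 classes): Gaussian background on a log-intensity-like
# scale, with a small planted set of class-informative genes whose means
# separate the classes.

#' Generate a synthetic expression dataset with planted informative genes
#'
#' Background features are `Normal(0, noise_sd)`. Each of the
#' `n_informative` planted genes carries a class-specific mean offset: class
#' `c` is shifted by `(c - 1) * effect_size` times a random per-gene sign,
#' so adjacent classes differ by `effect_size` (in units of `noise_sd` when
#' `noise_sd = 1`) on every informative gene. Labels are balanced up to
#' remainder. Optionally the background can be given block-equicorrelated
#' noise for harder instances.
#'
#' @param n_samples,n_features matrix dimensions (samples x genes).
#' @param n_classes number of classes (>= 2, at most `n_samples / 2` so
#'   every class has at least 2 samples).
#' @param n_informative number of planted informative genes
#'   (<= `n_features`).
#' @param effect_size between-class mean shift on informative genes.
#' @param noise_sd standard deviation of the background noise.
#' @param seed integer seed; the dataset is a pure function of the
#'   arguments.
#' @param block_cor equicorrelation within consecutive blocks of
#'   `block_size` background genes (0 = independent noise).
#' @param block_size block width used when `block_cor > 0`.
#' @return An object of class `expression_dataset`: `matrix`
#'   (samples x genes), `labels` (factor), `feature_names`,
#'   `informative_mask` (logical ground truth), `seed`.
#' @examples
#' ds <- generate_expression_dataset(62, 2000, 2, 20, 2, 1, seed = 1)
#' dim(ds$matrix)
#' table(ds$labels)
#' @export
generate_expression_dataset <- function(n_samples, n_features,
                                        n_classes = 2, n_informative = 10,
                                        effect_size = 2, noise_sd = 1,
                                        seed = 1, block_cor = 0,
                                        block_size = 10) {
  stopifnot(n_samples >= 4, n_features >= 1,
            n_informative >= 0, noise_sd > 0, block_cor >= 0, block_cor < 1)
  if (n_informative > n_features) {
    stop("n_informative must not exceed n_features", call. = FALSE)
  }
  if (n_classes < 2 || n_classes > n_samples / 2) {
    stop("n_classes must be in [2, n_samples / 2] so every class has >= 2 samples",
         call. = FALSE)
  }
  set.seed(seed)
  labels <- factor(paste0("class", rep_len(seq_len(n_classes), n_samples)),
                   levels = paste0("class", seq_len(n_classes)))

  if (block_cor > 0) {
    n_blocks <- ceiling(n_features / block_size)
    blk <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_features)]
    Z <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    E <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    X <- noise_sd * (sqrt(block_cor) * Z[, blk, drop = FALSE] +
                       sqrt(1 - block_cor) * E)
  } else {
    X <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                n_samples, n_features)
  }

  informative <- logical(n_features)
  if (n_informative > 0) {
    idx <- sample.int(n_features, n_informative)
    informative[idx] <- TRUE
    signs <- sample(c(-1, 1), n_informative, replace = TRUE)
    shift <- outer(as.integer(labels) - 1L, signs) * effect_size
    X[, idx] <- X[, idx] + shift
  }

  feature_names <- sprintf("gene%0*d", nchar(n_features), seq_len(n_features))
  colnames(X) <- feature_names
  structure(list(matrix = X, labels = labels,
                 feature_names = feature_names,
                 informative_mask = informative,
                 seed = as.integer(seed)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset: %d samples x %d genes, %d classes, %d informative, seed %d>\n",
              nrow(x$matrix), ncol(x$matrix), nlevels(x$labels),
              sum(x$informative_mask), x$seed))
  invisible(x)
}

#' Write an expression dataset to CSV
#'
#' One row per sample, one column per gene (header = gene identifiers), plus
#' a final `label` column. The ground-truth informative mask, when present,
#' is persisted as a two-column sidecar CSV at `<path>.mask`.
#'
#' @param ds an `expression_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- as.data.frame(format(ds$matrix, digits = 17, trim = TRUE,
                             scientific = TRUE),
                      check.names = FALSE)
  df$label <- as.character(ds$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ds$informative_mask)) {
    utils::write.csv(data.frame(feature = ds$feature_names,
                                informative = as.integer(ds$informative_mask)),
                     paste0(path, ".mask"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an expression dataset from CSV
#'
#' Expects the layout written by [write_dataset()]: samples in rows, gene
#' columns, and a `label` column. A `<path>.mask` sidecar, when present,
#' restores the ground-truth informative mask.
#'
#' @param path CSV path.
#' @return An `expression_dataset` (with `seed = NA`).
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) {
    stop("dataset file '", path, "' contains no samples", call. = FALSE)
  }
  if (!"label" %in% names(df)) {
    stop("dataset file '", path, "' is missing the required 'label' column",
         call. = FALSE)
  }
  labels <- factor(df$label)
  df$label <- NULL
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    stop("dataset file '", path, "' has non-numeric expression values",
         call. = FALSE)
  }
  mask <- NULL
  mask_path <- paste0(path, ".mask")
  if (file.exists(mask_path)) {
    m <- utils::read.csv(mask_path)
    mask <- as.logical(m$informative[match(colnames(X), m$feature)])
  }
  structure(list(matrix = X, labels = labels,
                 feature_names = colnames(X),
                 informative_mask = mask,
                 seed = NA_integer_),
            class = "expression_dataset")
}
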