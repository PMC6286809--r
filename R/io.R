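## File formats: headered TSV/CSV throughout. Replicate data files have
## rows = replicates and columns = metabolites; square matrices carry both
## a header row and a label column; fluctuation vectors are single-row
## headered tables. Metabolite order is taken from headers and preserved.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.check_numeric_cells <- function(df, path) {
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) | df[[j]] %in% c("", "NA") | is.na(df[[j]]))
    if (length(bad) > 0L) {
      stop("non-numeric or missing cell in ", path, " at row ", bad[1L],
           ", column ", j, " ('", df[[j]][bad[1L]], "')")
    }
    df[[j]] <- v
  }
  df
}

#' Read a typed matrix or vector from a headered TSV/CSV file
#'
#' @param path file path; delimiter inferred from the extension (`.csv`
#'   comma, otherwise tab).
#' @param kind one of `"data"` (replicates x metabolites, returns a
#'   [replicate_dataset()]), `"covariance"` or `"adjacency"` (square,
#'   header row + label column, returns a matrix), `"fluctuation"`
#'   (single-row headered table, returns a [fluctuation_spec()]).
#' @return typed object according to `kind`.
#' @export
read_matrix <- function(path, kind = c("data", "covariance", "fluctuation", "adjacency")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim_for(path)
  has_rownames <- kind %in% c("covariance", "adjacency")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      row.names = if (has_rownames) 1L else NULL,
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("malformed table in ", path, ": ", conditionMessage(e)))
  names_ <- colnames(df)
  if (anyDuplicated(names_)) {
    stop("duplicate metabolite names in ", path, ": ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  df <- .check_numeric_cells(df, path)
  M <- as.matrix(df)
  switch(kind,
    data = replicate_dataset(M, names_, "measured"),
    covariance = {
      if (nrow(M) != ncol(M)) stop("covariance in ", path, " is not square")
      rownames(M) <- rownames(df)
      as_covariance(M)
    },
    adjacency = {
      if (nrow(M) != ncol(M)) stop("adjacency in ", path, " is not square")
      rownames(M) <- rownames(df)
      M
    },
    fluctuation = {
      if (nrow(M) != 1L) stop("fluctuation vector in ", path, " must be a single data row")
      fluctuation_spec(M[1L, ], names = names_)
    })
}

#' Write a typed matrix or vector to a headered TSV/CSV file
#'
#' Values are written with 15 significant digits so that a write/read
#' round trip is lossless to at least 12 significant digits.
#'
#' @param x object to write (`replicate_dataset`, matrix, or
#'   `fluctuation_spec`).
#' @param path output path; delimiter inferred from the extension.
#' @param kind as in [read_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, kind = c("data", "covariance", "fluctuation", "adjacency")) {
  kind <- match.arg(kind)
  sep <- .delim_for(path)
  fmt <- function(M) {
    out <- format(M, digits = 15, scientific = NA, trim = TRUE)
    dim(out) <- dim(M); dimnames(out) <- dimnames(M)
    out
  }
  if (kind == "data") {
    stopifnot(inherits(x, "replicate_dataset"))
    utils::write.table(fmt(x$matrix), path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else if (kind == "fluctuation") {
    M <- matrix(as.numeric(x), nrow = 1, dimnames = list(NULL, names(x)))
    utils::write.table(fmt(M), path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    M <- as.matrix(x)
    if (is.null(rownames(M))) rownames(M) <- colnames(M)
    utils::write.table(fmt(M), path, sep = sep, quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

#' Read a prior-knowledge mask from a 3-column TSV/CSV
#'
#' Columns: source metabolite (the influencing one, Jacobian column),
#' target metabolite (the affected one, Jacobian row), and `zero` or
#' `nonzero`. Names are resolved against `metabolite_names`; duplicates are
#' deduplicated with a warning; contradictory entries error.
#'
#' @param path file path.
#' @param metabolite_names ordered metabolite labels of the dataset.
#' @return `prior_mask`.
#' @export
read_prior_mask <- function(path, metabolite_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  n <- length(metabolite_names)
  info <- file.info(path)
  if (info$size == 0L) return(empty_mask(n))
  df <- utils::read.table(path, header = FALSE, sep = .delim_for(path),
                          col.names = c("source", "target", "type"),
                          colClasses = "character")
  if (nrow(df) == 0L) return(empty_mask(n))
  unknown <- setdiff(unique(c(df$source, df$target)), metabolite_names)
  if (length(unknown) > 0L) {
    stop("unknown metabolite name(s) in prior mask: ",
         paste(unknown, collapse = ", "))
  }
  bad <- setdiff(unique(df$type), c("zero", "nonzero"))
  if (length(bad) > 0L) stop("prior mask type must be 'zero' or 'nonzero', got: ",
                             paste(bad, collapse = ", "))
  i <- match(df$target, metabolite_names)   # affected metabolite = row
  j <- match(df$source, metabolite_names)   # influencing metabolite = column
  key <- paste(i, j, df$type)
  if (anyDuplicated(key)) {
    warning("duplicate prior mask entries deduplicated")
    keep <- !duplicated(key)
    df <- df[keep, ]; i <- i[keep]; j <- j[keep]
  }
  pos_key <- paste(i, j)
  contradictory <- pos_key[duplicated(pos_key)]
  if (length(contradictory) > 0L) {
    stop("contradictory prior mask: position(s) listed as both zero and nonzero")
  }
  prior_mask(known_zero = cbind(i, j)[df$type == "zero", , drop = FALSE],
             known_nonzero = cbind(i, j)[df$type == "nonzero", , drop = FALSE],
             n = n)
}

#' Export an inferred network to disk
#'
#' Writes the consensus 0/1 adjacency matrix (TSV, metabolite labels), a
#' 3-column directed edge list (source, target, fitted Jacobian value;
#' SIF-style import friendly) and the fractional support matrix.
#'
#' @param result `inference_result`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
export_network <- function(result, dir, prefix = "network") {
  stopifnot(inherits(result, "inference_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(adjacency = file.path(dir, paste0(prefix, "_adjacency.tsv")),
             edges = file.path(dir, paste0(prefix, "_edges.tsv")),
             support = file.path(dir, paste0(prefix, "_support.tsv")))
  write_matrix(result$structure, paths["adjacency"], "adjacency")
  write_matrix(result$support, paths["support"], "adjacency")
  idx <- which(result$structure == 1L, arr.ind = TRUE)
  edges <- data.frame(source = result$metabolite_names[idx[, "col"]],
                      target = result$metabolite_names[idx[, "row"]],
                      value = result$jacobian[idx])
  utils::write.table(edges, paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write a template configuration file with all defaults
#'
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path) {
  cfg <- ga_config()
  bounds <- community_bounds()
  sde <- sde_config()
  yaml::write_yaml(list(
    ga = cfg[setdiff(names(cfg), character(0))],
    community = unclass(bounds),
    sde = sde[c("fluctuations", "dt", "t_end", "burn_in", "n_replicates",
                "method", "seed")]), path)
  invisible(path)
}

#' Read a configuration file
#'
#' @param path YAML path as written by [write_config_template()]; missing
#'   sections or keys fall back to defaults.
#' @return list with `ga` (`ga_config`), `community` (`community_bounds`),
#'   `sde` (`sde_config`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fill <- function(ctor, vals) {
    defaults <- formals(ctor)
    args <- vals[intersect(names(vals), names(defaults))]
    do.call(ctor, args)
  }
  list(ga = fill(ga_config, raw$ga %||% list()),
       community = fill(community_bounds, raw$community %||% list()),
       sde = fill(sde_config, raw$sde %||% list()))
}

#' Write a run manifest sufficient to reproduce a run
#'
#' Records the package version, seed, configuration and MD5 checksums of
#' all input files.
#'
#' @param dir output directory.
#' @param config list of configuration objects.
#' @param seed master seed used.
#' @param input_paths character vector of input files.
#' @return manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed, input_paths = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "manifest.yaml")
  checksums <- if (length(input_paths)) {
    as.list(tools::md5sum(input_paths))
  } else list()
  yaml::write_yaml(list(
    package = "lyapnet",
    version = as.character(utils::packageVersion("lyapnet")),
    seed = seed,
    config = rapply(config, unclass, how = "replace"),
    input_checksums = checksums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), path)
  invisible(path)
}
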