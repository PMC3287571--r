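# File formats: expression TSV (genes x time, header of time labels),
# gold-standard TSV (regulator, target, flag), SIF export, and a plain-text
# model file with one named block per matrix. All writers emit deterministic
# row order; lines starting with '#' are treated as comments by all readers.

#' Read a time-series expression matrix from TSV
#'
#' Expects a header row of time labels (first column `gene`), then one row
#' per gene: gene id followed by numeric expression values. Lines starting
#' with `#` are ignored. Ragged rows, non-numeric cells and duplicated gene
#' ids are rejected with informative errors.
#'
#' @param path file path.
#' @return An [expression_dataset].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(keep) < 2L) stop("expression file needs a header and at least one gene row",
                              call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  if (n_col < 2L) stop("header must contain at least one time label", call. = FALSE)
  time_labels <- header[-1L]
  rows <- fields[-1L]
  line_no <- keep[-1L]
  gene_ids <- character(length(rows))
  values <- matrix(NA_real_, length(rows), n_col - 1L)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != n_col) {
      stop(sprintf("line %d: expected %d fields, found %d", line_no[i], n_col, length(r)),
           call. = FALSE)
    }
    gene_ids[i] <- r[1L]
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("line %d, column %d: non-numeric value '%s'",
                   line_no[i], bad + 1L, r[bad + 1L]), call. = FALSE)
    }
    values[i, ] <- v
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop(sprintf("duplicated gene id(s): %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  expression_dataset(values, gene_ids = gene_ids, time_labels = time_labels)
}

#' Write a time-series expression matrix to TSV
#'
#' @param data an [expression_dataset].
#' @param path file path.
#' @param comments optional character vector written as leading `#` lines.
#' @export
write_expression_tsv <- function(data, path, comments = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  body <- c(paste(c("gene", data$time_labels), collapse = "\t"),
            vapply(seq_len(data$l), function(i) {
              paste(c(data$gene_ids[i],
                      format(data$values[i, ], digits = 17, trim = TRUE,
                             scientific = FALSE)), collapse = "\t")
            }, character(1)))
  writeLines(c(comment_lines(comments), body), path)
  invisible(path)
}

#' Read a gold-standard network from TSV
#'
#' Accepts the GeneNetWeaver gold-standard dialect: one row per candidate
#' edge, `regulator<TAB>target<TAB>flag`, where flag `1` marks a true edge
#' and flag-`0` rows are ignored (a missing third column means 1).
#' Self-loop rows are skipped with a warning; malformed rows are errors
#' naming the line.
#'
#' @param path file path.
#' @param genes optional full gene universe; defaults to every gene
#'   mentioned in the file.
#' @return A [gene_network].
#' @export
read_goldstandard_tsv <- function(path, genes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  reg <- character(0); tgt <- character(0)
  seen <- character(0)
  for (k in keep) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || length(f) > 3L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      stop(sprintf("line %d: malformed gold-standard row", k), call. = FALSE)
    }
    flag <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3L])) else 1
    if (is.na(flag)) stop(sprintf("line %d: non-numeric flag '%s'", k, f[3L]),
                          call. = FALSE)
    seen <- c(seen, f[1L], f[2L])
    if (flag == 0) next
    if (f[1L] == f[2L]) {
      warning(sprintf("line %d: self-loop %s -> %s skipped", k, f[1L], f[2L]),
              call. = FALSE)
      next
    }
    reg <- c(reg, f[1L]); tgt <- c(tgt, f[2L])
  }
  if (is.null(genes)) genes <- sort(unique(seen))
  gene_network(genes, if (length(reg)) data.frame(regulator = reg, target = tgt,
                                                  weight = 1, stringsAsFactors = FALSE))
}

#' Write a directed network to TSV or SIF
#'
#' The TSV format mirrors the gold-standard dialect (`regulator`, `target`,
#' `1`); SIF lines read `regulator regulates target` (Cytoscape-loadable).
#' Rows are sorted by regulator then target so output is deterministic.
#'
#' @param network a [gene_network].
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @param comments optional `#` header lines (TSV only; SIF has no comment
#'   syntax).
#' @export
write_network <- function(network, path, format = c("tsv", "sif"), comments = NULL) {
  stopifnot(inherits(network, "gene_network"))
  format <- match.arg(format)
  e <- network$edges
  e <- e[order(e$regulator, e$target), , drop = FALSE]
  if (format == "tsv") {
    body <- if (nrow(e)) paste(e$regulator, e$target, "1", sep = "\t") else character(0)
    writeLines(c(comment_lines(comments), body), path)
  } else {
    body <- if (nrow(e)) paste(e$regulator, "regulates", e$target, sep = "\t") else character(0)
    writeLines(body, path)
  }
  invisible(path)
}

#' Write fitted model parameters as a structured text file
#'
#' One named block per quantity (`F`, `H`, `Q`, `R`, `mu0`, `Sigma0`,
#' `gene_ids`, scalars `m`, `l`, `loglik`), tab-separated rows, so fits are
#' inspectable and diffable.
#'
#' @param fit an `ssm_fit` from [em_fit] (or an [ssm_params]).
#' @param path file path.
#' @param comments optional `#` header lines.
#' @export
write_model <- function(fit, path, comments = NULL) {
  if (inherits(fit, "ssm_fit")) {
    params <- fit$params; gene_ids <- fit$gene_ids; loglik <- fit$loglik
  } else {
    stopifnot(inherits(fit, "ssm_params"))
    params <- fit; gene_ids <- default_gene_ids(fit$l); loglik <- NA_real_
  }
  fmt <- function(M) apply(as.matrix(M), 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = "\t"))
  lines <- c(comment_lines(comments),
             "ssmgrn-model\t1",
             paste("m", params$m, sep = "\t"),
             paste("l", params$l, sep = "\t"),
             paste("loglik", format(loglik, digits = 17), sep = "\t"),
             paste("gene_ids", paste(gene_ids, collapse = "\t"), sep = "\t"),
             "F", fmt(params$F),
             "H", fmt(params$H),
             "Q", fmt(params$Q),
             "R", fmt(params$R),
             "mu0", paste(format(params$mu0, digits = 17, trim = TRUE), collapse = "\t"),
             "Sigma0", fmt(params$Sigma0))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model file written by [write_model]
#'
#' @param path file path.
#' @return A list with `params` ([ssm_params]), `gene_ids` and `loglik`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!identical(strsplit(lines[1L], "\t")[[1L]][1L], "ssmgrn-model")) {
    stop("not an ssmgrn model file", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key_at <- vapply(fields, `[[`, character(1), 1L)
  get_scalar <- function(key) {
    i <- which(key_at == key)[1L]
    if (is.na(i)) stop(sprintf("model file missing block '%s'", key), call. = FALSE)
    fields[[i]][2L]
  }
  m <- as.integer(get_scalar("m")); l <- as.integer(get_scalar("l"))
  gene_ids <- fields[[which(key_at == "gene_ids")[1L]]][-1L]
  read_block <- function(key, nrow) {
    i <- which(key_at == key)[1L]
    if (is.na(i)) stop(sprintf("model file missing block '%s'", key), call. = FALSE)
    rows <- lapply(fields[(i + 1L):(i + nrow)], as.numeric)
    do.call(rbind, rows)
  }
  params <- ssm_params(F = read_block("F", m), H = read_block("H", l),
                       Q = read_block("Q", m), R = read_block("R", l),
                       mu0 = as.numeric(fields[[which(key_at == "mu0")[1L] + 1L]]),
                       Sigma0 = read_block("Sigma0", m))
  list(params = params, gene_ids = gene_ids,
       loglik = as.numeric(get_scalar("loglik")))
}

#' Write a connectivity matrix to TSV
#'
#' @param cm a [connectivity_matrix].
#' @param path file path.
#' @param comments optional `#` header lines.
#' @export
write_connectivity_tsv <- function(cm, path, comments = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  body <- c(paste(c("gene", cm$gene_ids), collapse = "\t"),
            vapply(seq_along(cm$gene_ids), function(i) {
              paste(c(cm$gene_ids[i],
                      format(cm$C[i, ], digits = 17, trim = TRUE)), collapse = "\t")
            }, character(1)))
  writeLines(c(comment_lines(comments), body), path)
  invisible(path)
}

comment_lines <- function(comments) {
  if (is.null(comments)) character(0) else paste0("# ", comments)
}
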