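# Domain containers and plain-text readers/writers for every table the
# pipeline touches: expression matrices, gene sets (GMT), mutation catalogs
# (MAF-like TSV with trinucleotide context), per-sample score tables and
# survival tables.

EXPRESSION_UNITS <- c("TPM", "RPKM", "LOG2_TPM1", "NORMALIZED")
SAMPLE_CLASSES <- c("CELL_LINE", "TUMOUR", "SINGLE_CELL")
DNA_BASES <- c("A", "C", "G", "T")

#' Construct an expression matrix container
#'
#' A thin S3 wrapper around a numeric genes-by-samples matrix that carries the
#' expression unit (`TPM`, `RPKM`, `LOG2_TPM1` for log2(TPM+1)-type values, or
#' `NORMALIZED` for variance-stabilised values) and a per-sample source class
#' (`CELL_LINE`, `TUMOUR`, `SINGLE_CELL`).
#'
#' @param values Numeric matrix, rows = genes, columns = samples; rownames and
#'   colnames are required and must be unique. All values must be finite, and
#'   non-negative for `TPM`/`RPKM`.
#' @param unit One of `"TPM"`, `"RPKM"`, `"LOG2_TPM1"`, `"NORMALIZED"`.
#' @param sample_class A single class recycled over samples, or a vector (one
#'   per sample, optionally named by sample).
#' @return An object of class `expression_matrix` with elements `values`,
#'   `unit`, `sample_class`.
#' @export
expression_matrix <- function(values, unit, sample_class = "CELL_LINE") {
  .check(is.matrix(values) && is.numeric(values),
         "'values' must be a numeric matrix")
  .check(!is.null(rownames(values)) && !is.null(colnames(values)),
         "'values' must have gene rownames and sample colnames")
  .check(!anyDuplicated(rownames(values)), "duplicate gene identifiers")
  .check(!anyDuplicated(colnames(values)), "duplicate sample identifiers")
  .check(all(is.finite(values)), "expression values must be finite")
  unit <- match.arg(unit, EXPRESSION_UNITS)
  if (unit %in% c("TPM", "RPKM")) {
    .check(all(values >= 0), sprintf("%s values must be >= 0", unit))
  }
  if (length(sample_class) == 1L) {
    sample_class <- rep(sample_class, ncol(values))
  }
  .check(length(sample_class) == ncol(values),
         "one sample_class per sample required")
  .check(all(sample_class %in% SAMPLE_CLASSES),
         paste("sample_class must be one of:",
               paste(SAMPLE_CLASSES, collapse = ", ")))
  names(sample_class) <- colnames(values)
  structure(list(values = values, unit = unit, sample_class = sample_class),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cls <- table(x$sample_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

genes <- function(x) rownames(x$values)
samples <- function(x) colnames(x$values)

#' Read a gene-by-sample expression table
#'
#' Expects a TSV with a header row of sample identifiers and gene identifiers
#' in the first column. Duplicate gene rows are collapsed by the per-sample
#' maximum, keeping the first-appearance row order.
#'
#' @param path Path to a tab-separated file.
#' @param unit Declared expression unit (see [expression_matrix()]).
#' @param sample_class Single class or named vector mapping sample id to class.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, unit, sample_class = "CELL_LINE") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("format error: expression table needs a header and at least one gene row: ",
         path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) {
    stop("format error: no sample columns in ", path, call. = FALSE)
  }
  n_col <- length(header)
  body <- fields[-1L]
  bad <- which(lengths(body) != n_col)
  if (length(bad)) {
    stop(sprintf("format error: row %d has %d fields, expected %d",
                 bad[1L] + 1L, lengths(body)[bad[1L]], n_col), call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  raw <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                byrow = TRUE)
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: non-numeric value '%s' at row %d, column %d (%s)",
                 raw[idx[1L], idx[2L]], idx[1L] + 1L, idx[2L] + 1L,
                 sample_ids[idx[2L]]), call. = FALSE)
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  if (anyDuplicated(gene_ids)) {
    keep <- unique(gene_ids)
    vals <- do.call(rbind, lapply(keep, function(g) {
      apply(vals[gene_ids == g, , drop = FALSE], 2L, max)
    }))
    rownames(vals) <- keep
  }
  if (is.null(names(sample_class)) || length(sample_class) == 1L) {
    cls <- sample_class
  } else {
    missing <- setdiff(sample_ids, names(sample_class))
    .check(length(missing) == 0L,
           paste("no sample_class for:", paste(missing, collapse = ", ")))
    cls <- unname(sample_class[sample_ids])
  }
  expression_matrix(vals, unit = unit, sample_class = cls)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces doubles bitwise.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(x, path) {
  .check(inherits(x, "expression_matrix"), "'x' must be an expression_matrix")
  v <- x$values
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("gene", colnames(v)), collapse = "\t"), body), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description (discarded), then members, all
#' tab-separated. Duplicate members are stored once.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("format error: GMT line %d has fewer than 3 fields", bad[1L]),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Construct a mutation record table
#'
#' Each row is one somatic SNV with its immediate 5' and 3' neighbouring
#' bases. Bases are upper-cased and validated against A/C/G/T; reference and
#' alternate bases must differ.
#'
#' @param sample Sample identifiers.
#' @param ref,alt Reference and alternate bases.
#' @param five_prime,three_prime Neighbouring bases.
#' @return A data.frame of class `mutation_table` with those five columns.
#' @export
mutation_records <- function(sample, ref, alt, five_prime, three_prime) {
  up <- function(x) toupper(as.character(x))
  ref <- up(ref); alt <- up(alt)
  five_prime <- up(five_prime); three_prime <- up(three_prime)
  bases <- c(ref, alt, five_prime, three_prime)
  if (!all(bases %in% DNA_BASES)) {
    stop("parse error: base not in {A,C,G,T}: ",
         paste(unique(setdiff(bases, DNA_BASES)), collapse = ", "),
         call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("parse error: ref == alt in mutation record", call. = FALSE)
  }
  out <- data.frame(sample = as.character(sample), ref = ref, alt = alt,
                    five_prime = five_prime, three_prime = three_prime,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Read a MAF-like somatic SNV table
#'
#' Requires columns `sample`, `ref`, `alt`, and either a 3-mer `context`
#' column (whose middle base must equal `ref`) or explicit `five_prime` /
#' `three_prime` columns. A `gene` column, if present, is carried through for
#' downstream per-gene mutation status.
#'
#' @param path Path to a tab-separated file with a header.
#' @return A `mutation_table` data.frame (see [mutation_records()]), with a
#'   `gene` column when the input had one. Row order follows the file.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .check(nrow(df) > 0L, paste("format error: empty mutation table:", path))
  need <- c("sample", "ref", "alt")
  .check(all(need %in% names(df)),
         "format error: mutation table requires columns sample, ref, alt")
  if ("context" %in% names(df)) {
    ctx <- toupper(df$context)
    .check(all(nchar(ctx) == 3L),
           "parse error: context must be a 3-mer")
    five <- substr(ctx, 1L, 1L)
    mid <- substr(ctx, 2L, 2L)
    three <- substr(ctx, 3L, 3L)
    bad <- which(mid != toupper(df$ref))
    if (length(bad)) {
      stop(sprintf("consistency error: context middle base '%s' != ref '%s' at data row %d",
                   mid[bad[1L]], toupper(df$ref)[bad[1L]], bad[1L]),
           call. = FALSE)
    }
  } else {
    .check(all(c("five_prime", "three_prime") %in% names(df)),
           "format error: need 'context' or 'five_prime'/'three_prime' columns")
    five <- df$five_prime
    three <- df$three_prime
  }
  out <- mutation_records(df$sample, df$ref, df$alt, five, three)
  if ("gene" %in% names(df)) out$gene <- as.character(df$gene)
  out
}

#' Construct a per-sample score table
#'
#' Holds one scalar score per sample (ESTIMATE-style immune/stromal scores,
#' immune DEG values, MITF/AXL cell scores, skin scores, ...).
#'
#' @param sample Sample identifiers (unique).
#' @param score Finite numeric values, one per sample.
#' @param score_name Label for the score.
#' @return A data.frame of class `score_table` with columns `sample`, `score`
#'   and attribute `score_name`.
#' @export
score_table <- function(sample, score, score_name = "score") {
  sample <- as.character(sample)
  .check(!anyDuplicated(sample), "duplicate sample identifiers in score table")
  .check(length(score) == length(sample), "one score per sample required")
  .check(all(is.finite(score)), "scores must be finite")
  out <- data.frame(sample = sample, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "score_name") <- score_name
  class(out) <- c("score_table", "data.frame")
  out
}

#' Read a two-column per-sample score TSV
#'
#' @param path TSV with header; first column sample ids, second column scores.
#' @param score_name Label for the score (defaults to the second header name).
#' @return A [score_table()].
#' @export
read_score_table <- function(path, score_name = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .check(ncol(df) >= 2L, paste("format error: score table needs 2 columns:", path))
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(vals)) {
    stop(sprintf("parse error: non-numeric score at data row %d",
                 which(is.na(vals))[1L]), call. = FALSE)
  }
  score_table(df[[1L]], vals,
              score_name = if (is.null(score_name)) names(df)[2L] else score_name)
}

#' Construct a survival table
#'
#' @param sample Sample identifiers.
#' @param time Non-negative follow-up times (months).
#' @param event Logical; `TRUE` if death was observed at `time`.
#' @param group Optional group labels.
#' @return A data.frame of class `survival_table`.
#' @export
survival_records <- function(sample, time, event, group = NULL) {
  .check(all(is.finite(time)) && all(time >= 0), "survival times must be >= 0")
  .check(is.logical(event) && !anyNA(event), "'event' must be logical")
  out <- data.frame(sample = as.character(sample), time = as.numeric(time),
                    event = event, stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- as.character(group)
  class(out) <- c("survival_table", "data.frame")
  out
}
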