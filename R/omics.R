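# Siderophore biosynthesis gene quantification from homology hit tables.
#
# Reads mapping to a gene orthologue are length-normalized ("full-length
# copies"): each read contributes read_length_bp / (3 * subject_length_aa)
# of a complete gene. Per-sample orthologue totals are then divided by the
# full-length copies of the universal single-copy marker rpoA, yielding
# copies per genome (DNA) or transcripts per rpoA transcript (RNA).

HIT_COLUMNS <- c("qseqid", "sseqid", "evalue", "bitscore", "qlen", "slen")

#' Parse a tabular homology hit file
#'
#' Reads a BLAST/DIAMOND-style tabular file with columns
#' `qseqid sseqid evalue bitscore qlen slen` and an optional seventh
#' `genus` column. `qlen` is the query (read) length in base pairs and
#' `slen` the subject (protein) length in amino acids. A header line is
#' detected and skipped if present.
#'
#' @param path Path to a TSV hit table.
#' @param lenient If `TRUE`, malformed rows are skipped with a warning
#'   naming their line numbers; if `FALSE` they raise an error.
#' @return A data.frame of hits with columns `read_id`, `subject_id`,
#'   `evalue`, `bitscore`, `read_length_bp`, `subject_length_aa` and
#'   optionally `genus` (and `sample_id` if present in the file).
#' @export
parse_hit_table <- function(path, lenient = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty hit table: ", path)
    return(empty_hits())
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- any(tolower(first) %in% c("qseqid", "sseqid", "evalue"))
  body <- if (has_header) lines[-1] else lines
  lineno <- seq_along(lines)[if (has_header) -1L else TRUE]
  if (!length(body)) {
    warning("hit table has a header but no rows: ", path)
    return(empty_hits())
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 6L &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      !is.na(suppressWarnings(as.numeric(f[5]))) &&
      !is.na(suppressWarnings(as.numeric(f[6])))
  }, logical(1))
  if (any(!ok)) {
    msg <- paste0("malformed hit rows at line(s): ",
                  paste(lineno[!ok], collapse = ", "))
    if (!lenient) stop(msg, call. = FALSE)
    warning(msg)
    fields <- fields[ok]
  }
  if (!length(fields)) return(empty_hits())

  hits <- data.frame(
    read_id = vapply(fields, `[`, "", 1L),
    subject_id = vapply(fields, `[`, "", 2L),
    evalue = as.numeric(vapply(fields, `[`, "", 3L)),
    bitscore = as.numeric(vapply(fields, `[`, "", 4L)),
    read_length_bp = as.numeric(vapply(fields, `[`, "", 5L)),
    subject_length_aa = as.numeric(vapply(fields, `[`, "", 6L)),
    stringsAsFactors = FALSE
  )
  if (all(vapply(fields, length, 0L) >= 7L)) {
    hits$genus <- vapply(fields, `[`, "", 7L)
  }
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  data.frame(read_id = character(0), subject_id = character(0),
             evalue = numeric(0), bitscore = numeric(0),
             read_length_bp = numeric(0), subject_length_aa = numeric(0),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  need <- c("read_id", "subject_id", "evalue", "read_length_bp",
            "subject_length_aa")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("hit table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits)) {
    if (any(hits$read_length_bp < 1)) stop("read lengths must be >= 1 bp",
                                           call. = FALSE)
    if (any(hits$subject_length_aa < 1)) stop("subject lengths must be >= 1 aa",
                                              call. = FALSE)
    if (any(hits$evalue < 0)) stop("E-values must be >= 0", call. = FALSE)
  }
  invisible(hits)
}

#' Write a hit table in the package's TSV dialect
#'
#' @param hits Hit data.frame as returned by [parse_hit_table()].
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @export
write_hit_table <- function(hits, path, header = TRUE) {
  cols <- c("read_id", "subject_id", "evalue", "bitscore",
            "read_length_bp", "subject_length_aa")
  out <- hits[, cols]
  names(out) <- HIT_COLUMNS
  if (!is.null(hits$genus)) out$genus <- hits$genus
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Filter hits by E-value
#'
#' Hits were annotated upstream at a permissive cutoff (1e-3); the
#' analysis applies a stricter post hoc cutoff, 1e-5 by default.
#'
#' @param hits Hit data.frame.
#' @param evalue_cutoff Keep hits with `evalue <= evalue_cutoff`.
#' @param quiet Suppress the removed-hit count message.
#' @return Filtered hit data.frame; the number removed is reported via
#'   `message()` and attached as attribute `"n_removed"`.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-5, quiet = FALSE) {
  stopifnot(evalue_cutoff > 0)
  keep <- hits$evalue <= evalue_cutoff
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet) message(sum(!keep), " hit(s) removed at E-value cutoff ",
                      format(evalue_cutoff))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Full-length copies contributed by one hit
#'
#' A read of length L bp matching a protein of length S aa contributes
#' L / (3 S) full-length gene copies (3 bp per codon).
#'
#' @param read_length_bp Read length(s), bp.
#' @param subject_length_aa Subject protein length(s), aa.
#' @return Numeric, full-length copies.
#' @examples
#' length_normalized_copies(300, 100)  # 1.0
#' length_normalized_copies(150, 400)  # 0.125
#' @export
length_normalized_copies <- function(read_length_bp, subject_length_aa) {
  if (any(subject_length_aa <= 0)) {
    stop("subject length must be > 0 aa", call. = FALSE)
  }
  read_length_bp / (3 * subject_length_aa)
}

#' Sum length-normalized copies per sample and orthologue
#'
#' @param hits Hit data.frame; if it has no `sample_id` column all hits
#'   are treated as one sample named `"sample1"`.
#' @param dedupe Warn on duplicated `read_id` within a sample and keep the
#'   lowest-E-value hit (inputs are expected max-one-hit-per-read).
#' @return Object of class `gene_abundance`: a sample x orthologue
#'   numeric matrix of full-length copies with attributes
#'   `normalized = FALSE`.
#' @export
count_orthologues <- function(hits, dedupe = TRUE) {
  if (is.null(hits$sample_id)) hits$sample_id <- "sample1"
  # fix the table dimensions before any dedupe so an orthologue whose
  # every hit loses the duplicate tie-break still appears as a zero column
  samples <- sort(unique(hits$sample_id))
  orthos <- sort(unique(hits$subject_id))
  if (dedupe && nrow(hits)) {
    key <- paste(hits$sample_id, hits$read_id, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate read_id(s) within a sample; keeping lowest E-value")
      ord <- order(hits$evalue)
      hits <- hits[ord, , drop = FALSE]
      hits <- hits[!duplicated(paste(hits$sample_id, hits$read_id,
                                     sep = "\r")), , drop = FALSE]
    }
  }
  copies <- length_normalized_copies(hits$read_length_bp,
                                     hits$subject_length_aa)
  m <- matrix(0, nrow = length(samples), ncol = length(orthos),
              dimnames = list(samples, orthos))
  if (nrow(hits)) {
    agg <- tapply(copies, list(hits$sample_id, hits$subject_id), sum)
    agg[is.na(agg)] <- 0
    m[rownames(agg), colnames(agg)] <- agg
  }
  structure(m, class = c("gene_abundance", "matrix", "array"),
            normalized = FALSE)
}

#' @export
print.gene_abundance <- function(x, ...) {
  cat("Gene abundance table (",
      if (isTRUE(attr(x, "normalized"))) "rpoA-normalized" else "raw",
      " full-length copies): ", nrow(x), " sample(s) x ", ncol(x),
      " orthologue(s)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Normalize a raw abundance table by per-sample rpoA copies
#'
#' Divides every entry by that sample's full-length rpoA copies, giving
#' copies per genome (metagenomes) or transcripts per rpoA transcript
#' (metatranscriptomes). Exactly invariant to duplicating every read.
#'
#' @param table `gene_abundance` matrix from [count_orthologues()].
#' @param marker Marker orthologue column name, default `"rpoA"`.
#' @param drop_marker Drop the marker column (now identically 1) from the
#'   output; default `TRUE`.
#' @return `gene_abundance` matrix with attribute `normalized = TRUE` and
#'   per-sample marker copies in attribute `"marker_copies"`.
#' @export
normalize_by_rpoa <- function(table, marker = "rpoA", drop_marker = TRUE) {
  if (isTRUE(attr(table, "normalized"))) {
    stop("table is already normalized", call. = FALSE)
  }
  if (!marker %in% colnames(table)) {
    stop("marker orthologue '", marker, "' absent from table", call. = FALSE)
  }
  mk <- table[, marker]
  zero <- mk <= 0
  if (any(zero)) {
    stop("cannot normalize: zero ", marker, " copies in sample(s): ",
         paste(rownames(table)[zero], collapse = ", "), call. = FALSE)
  }
  out <- sweep(unclass(table), 1, mk, "/")
  if (drop_marker) out <- out[, colnames(out) != marker, drop = FALSE]
  structure(out, class = c("gene_abundance", "matrix", "array"),
            normalized = TRUE, marker = marker, marker_copies = mk)
}

#' Aggregate orthologue abundances into siderophore classes
#'
#' Siderophore biosynthesis genes fall into four biochemical classes by
#' the ligand moiety of the product: hydroxamate, catecholate,
#' mixed-ligand, carboxylate. The class value is the exact sum of its
#' member orthologues; the marker gene is excluded.
#'
#' @param table `gene_abundance` matrix.
#' @param classmap Data.frame with columns `orthologue` and `class`, or a
#'   named character vector `orthologue -> class`.
#' @param marker Marker orthologue to exclude, default `"rpoA"`.
#' @return `gene_abundance`-classed sample x class matrix.
#' @export
aggregate_by_class <- function(table, classmap, marker = "rpoA") {
  if (is.data.frame(classmap)) {
    cm <- stats::setNames(as.character(classmap$class),
                          as.character(classmap$orthologue))
  } else {
    cm <- classmap
  }
  orthos <- setdiff(colnames(table), marker)
  unmapped <- orthos[!orthos %in% names(cm)]
  if (length(unmapped)) {
    stop("orthologue(s) missing from class map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  classes <- sort(unique(unname(cm)))
  out <- matrix(0, nrow = nrow(table), ncol = length(classes),
                dimnames = list(rownames(table), classes))
  for (cl in classes) {
    members <- intersect(orthos, names(cm)[cm == cl])
    if (length(members)) {
      out[, cl] <- rowSums(unclass(table)[, members, drop = FALSE])
    }
  }
  structure(out, class = c("gene_abundance", "matrix", "array"),
            normalized = attr(table, "normalized") %||% FALSE)
}

#' Per-genus ratio of a gene to a single-copy marker
#'
#' The genus-level ratio of full-length gene copies (e.g. desB) to marker
#' copies (rpoA) estimates the fraction of genomes in that genus carrying
#' the gene. Genera whose marker count falls below `marker_floor` are
#' flagged rather than silently dropped; a genus with marker copies of 0
#' gets an `NA` ratio and a flag.
#'
#' @param hits Filtered hit data.frame with a `genus` column.
#' @param gene Gene orthologue, default `"desB"`.
#' @param marker Marker orthologue, default `"rpoA"`.
#' @param marker_floor Flag genera with marker copies below this floor
#'   (default 0.1 full-length copies).
#' @return Data.frame with columns `genus`, `gene_copies`,
#'   `marker_copies`, `ratio`, `flag`.
#' @export
genus_marker_ratio <- function(hits, gene = "desB", marker = "rpoA",
                               marker_floor = 0.1) {
  if (is.null(hits$genus)) {
    stop("hits must carry a 'genus' column", call. = FALSE)
  }
  sub <- hits[hits$subject_id %in% c(gene, marker), , drop = FALSE]
  genera <- sort(unique(sub$genus))
  copies_of <- function(g, id) {
    rows <- sub$genus == g & sub$subject_id == id
    sum(length_normalized_copies(sub$read_length_bp[rows],
                                 sub$subject_length_aa[rows]))
  }
  gene_c <- vapply(genera, copies_of, 0, id = gene)
  mark_c <- vapply(genera, copies_of, 0, id = marker)
  ratio <- ifelse(mark_c > 0, gene_c / mark_c, NA_real_)
  flag <- ifelse(mark_c == 0, "marker absent",
                 ifelse(mark_c < marker_floor, "marker below floor", ""))
  data.frame(genus = genera, gene_copies = unname(gene_c),
             marker_copies = unname(mark_c), ratio = unname(ratio),
             flag = unname(flag), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-feature fold change and t-test between two substrate groups
#'
#' Compares, feature by feature, abundance tables from two substrates
#' (e.g. weathered basalt grains vs surrounding soil): fold change of
#' group means and a two-sided two-sample t-test (Welch by default). No
#' multiplicity correction is applied here; p-values are reported raw.
#'
#' @param tableA,tableB `gene_abundance` matrices (samples x features)
#'   with identical feature columns; >= 2 samples each.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data.frame with columns `feature`, `mean_A`, `mean_B`, `fold`
#'   (mean_A / mean_B), `t`, `df`, `p`.
#' @export
compare_substrates <- function(tableA, tableB, var_equal = FALSE) {
  feats <- colnames(tableA)
  if (!identical(feats, colnames(tableB))) {
    stop("tables must share identical feature columns", call. = FALSE)
  }
  if (nrow(tableA) < 2L || nrow(tableB) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  res <- lapply(feats, function(f) {
    a <- unclass(tableA)[, f]; b <- unclass(tableB)[, f]
    fold <- if (mean(b) != 0) mean(a) / mean(b) else NA_real_
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no variance anywhere
      if (mean(a) == mean(b)) {
        tt <- list(statistic = 0, parameter = NA_real_, p.value = 1)
      } else {
        tt <- list(statistic = Inf * sign(mean(a) - mean(b)),
                   parameter = NA_real_, p.value = 0)
      }
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    data.frame(feature = f, mean_A = mean(a), mean_B = mean(b),
               fold = fold, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
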