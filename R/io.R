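# File formats: expression TSV / GCT 1.2, GMT, RNK, BED6 / narrowPeak,
# bedGraph, JASPAR PFM. Interval files are exposed as GRanges (1-based,
# closed) and converted from/to BED convention (0-based, half-open) at the
# boundary.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Tab-delimited, first column gene identifiers, header row of sample
#' identifiers.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-sample expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read / write GCT 1.2 expression files
#'
#' The GCT 1.2 dialect: a `#1.2` version line, a dimensions line, then a
#' header `Name`, `Description`, sample ids.
#'
#' @param path file path.
#' @return `read_gct`: numeric matrix with gene rownames and sample colnames.
#' @export
read_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!startsWith(lines[1L], "#1.2")) {
    stop("not a GCT 1.2 file: ", path)
  }
  df <- utils::read.delim(path,
    skip = 2L, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_gct
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @export
write_gct <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  df <- data.frame(
    Name = rownames(mat), Description = "na", mat,
    check.names = FALSE
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-delimited.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ranked gene lists in RNK format
#'
#' Two tab-delimited columns: gene id and score. The returned vector is the
#' canonical ranked-list representation: a named numeric vector sorted in
#' strictly descending score order, score ties broken by gene id ascending.
#'
#' @param path file path.
#' @return `read_rnk`: named numeric vector in ranked order.
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path,
    header = FALSE, stringsAsFactors = FALSE,
    col.names = c("gene_id", "score")
  )
  as_ranked_list(stats::setNames(as.numeric(df$score), df$gene_id))
}

#' @rdname read_rnk
#' @param ranked named numeric vector.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(
    data.frame(gene_id = names(ranked), score = unname(ranked)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read genomic intervals from BED6 or narrowPeak files
#'
#' Coordinates on file are 0-based half-open and converted to the 1-based
#' closed convention of `GRanges`. narrowPeak files (10 columns) carry their
#' extra statistics as metadata columns.
#'
#' @param path file path.
#' @return `GRanges` with `name` and `score` metadata (plus `signalValue`,
#'   `pValue`, `qValue`, `peak` for narrowPeak input).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  nc <- ncol(df)
  if (nc < 3L) stop("malformed interval file (fewer than 3 columns): ", path)
  if (any(df[[2]] < 0) || any(df[[3]] <= df[[2]])) {
    stop("malformed interval: require 0 <= start < end in ", path)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (nc >= 6L) ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*") else "*"
  )
  if (nc >= 4L) gr$name <- as.character(df[[4]])
  if (nc >= 5L) gr$score <- suppressWarnings(as.numeric(df[[5]]))
  if (nc >= 10L) {
    gr$signalValue <- df[[7]]
    gr$pValue <- df[[8]]
    gr$qValue <- df[[9]]
    gr$peak <- df[[10]]
  }
  gr
}

#' Write intervals as BED6
#'
#' @param gr `GRanges`; `name` and `score` metadata are used when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", ".",
      as.character(GenomicRanges::strand(gr))
    )
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read / write coverage tracks in bedGraph format
#'
#' @param path file path.
#' @return `read_bedgraph`: `GRanges` with a numeric `score` column, sorted,
#'   non-overlapping.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    score = as.numeric(df[[4]])
  )
  gr <- GenomicRanges::sort(gr)
  self_hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(self_hits) > 0L) {
    stop("bedGraph intervals overlap: ", path)
  }
  gr
}

#' @rdname read_bedgraph
#' @param track `GRanges` with a `score` column.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    score = track$score
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a position frequency matrix in JASPAR format
#'
#' Accepts the bracketed JASPAR layout (`>MA0046.1 HNF1A` header, then four
#' rows `A [ ... ]` .. `T [ ... ]`) or a plain four-row count matrix.
#' Counts are converted to per-position probabilities; the background
#' defaults to uniform.
#'
#' @param path file path.
#' @param background optional length-4 probability vector over A, C, G, T.
#' @return a `pwm` object: list with `id`, `width`, `prob` (4 x width
#'   probability matrix, rows A, C, G, T) and `background`.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- "motif"
  if (startsWith(lines[1L], ">")) {
    id <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("JASPAR file needs 4 base rows: ", path)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  w <- unique(vapply(rows, length, 1L))
  if (length(w) != 1L) stop("ragged matrix rows in ", path)
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  new_pwm(id, counts, background)
}

#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param counts 4 x width matrix of counts or probabilities (rows A, C, G,
#'   T).
#' @param background length-4 probability vector over A, C, G, T.
#' @return a `pwm` object (see [read_jaspar()]).
#' @export
new_pwm <- function(id, counts, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM needs 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("PWM entries must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("PWM column with zero total")
  prob <- sweep(counts, 2L, cs, "/")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1")
  }
  names(background) <- c("A", "C", "G", "T")
  structure(
    list(
      id = id, width = ncol(prob), prob = prob,
      background = background
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "width", x$width, "\n")
  print(round(x$prob, 3))
  invisible(x)
}
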