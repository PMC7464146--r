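#' Read a BED file of intervals
#'
#' Strict reader for 3+ column tab-separated BED (0-based half-open).
#' Malformed lines (fewer than 3 fields, non-numeric coordinates, or
#' end < start) raise an error naming the offending line.  Extra columns
#' are preserved (column 4 becomes `name`, 5 `score`, further columns
#' keep `V` names).  Input in 1-based inclusive coordinates can be
#' shifted on read with `one_based = TRUE` (start - 1).
#'
#' @param path file path.
#' @param one_based logical; input coordinates are 1-based inclusive.
#' @return data.frame with chrom, start, end and any extra columns.
#' @export
read_bed <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(),
                                        start = integer(), end = integer(),
                                        stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) stop("line ", i, ": fewer than 3 tab-separated fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("line ", i, ": non-numeric coordinates")
    if (e < s - one_based) stop("line ", i, ": end < start")
  }
  ncol <- max(lengths(fields))
  df <- as.data.frame(do.call(rbind, lapply(fields, function(f)
    c(f, rep(NA, ncol - length(f))))), stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol >= 4) names(df)[4] <- "name"
  if (ncol >= 5) names(df)[5] <- "score"
  df$start <- as.integer(as.numeric(df$start)) - as.integer(one_based)
  df$end <- as.integer(as.numeric(df$end))
  df
}

#' Write intervals as BED
#'
#' Tab-separated, no header, 0-based half-open.  A `name` column (or the
#' column named by `name_col`) becomes BED column 4; remaining columns
#' follow in order.
#'
#' @param intervals data.frame with chrom, start, end (+ extras).
#' @param path output path.
#' @param name_col column to place as BED column 4.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name_col = "name") {
  core <- intervals[, c("chrom", "start", "end")]
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  if (name_col %in% extra) extra <- c(name_col, setdiff(extra, name_col))
  out <- cbind(core, intervals[, extra, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a TSV matrix with an id column
#'
#' Matrices are stored as TSV with a header row; the first column holds
#' row ids (gene/probe/DMR/peak), remaining columns are samples.
#'
#' @param path file path.
#' @return numeric matrix with rownames from the id column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param mat matrix to write.
#' @param id_name header name for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
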