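#' DNA alignment container
#'
#' A `dna_alignment` is a character matrix of single upper-case IUPAC
#' nucleotide symbols (plus `-` for gaps and `?`/`N` for missing data),
#' rows named by taxon, together with an optional partition table mapping
#' genes to 1-based inclusive column ranges.
#'
#' @param seqs Character matrix (taxa x sites) or named character vector
#'   of equal-length sequence strings.
#' @param partitions Optional `data.frame` with columns `gene`, `start`,
#'   `end` (1-based inclusive).
#' @return An object of class `"dna_alignment"`.
#' @export
dna_alignment <- function(seqs, partitions = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    nc <- unique(nchar(seqs))
    if (length(nc) != 1L)
      stop("sequences differ in length; first offender: '",
           names(seqs)[which(nchar(seqs) != nchar(seqs)[1])[1]], "'")
    m <- t(vapply(seqs, function(s) strsplit(s, "")[[1L]],
                  character(nc)))
  } else {
    m <- as.matrix(seqs)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon name(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  ok <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
          "B", "D", "H", "V", "N", "-", "?", ".")
  bad <- setdiff(unique(as.vector(m)), ok)
  if (length(bad))
    stop("unrecognized sequence symbol(s): ", paste(bad, collapse = ", "))
  obj <- structure(list(seq = m, partitions = NULL), class = "dna_alignment")
  if (!is.null(partitions)) obj <- set_partitions(obj, partitions)
  obj
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x$seq), "taxa x", ncol(x$seq), "sites")
  if (!is.null(x$partitions))
    cat(";", nrow(x$partitions), "partition(s)")
  cat("\n")
  invisible(x)
}

#' @rdname dna_alignment
#' @param x A `dna_alignment`.
#' @export
n_taxa <- function(x) nrow(x$seq)

#' @rdname dna_alignment
#' @export
alignment_length <- function(x) ncol(x$seq)

#' @rdname dna_alignment
#' @export
taxa_names <- function(x) rownames(x$seq)

#' Attach a partition table to an alignment
#'
#' @param aln A `dna_alignment`.
#' @param partitions `data.frame` with columns `gene`, `start`, `end`
#'   (1-based inclusive column ranges).
#' @return The alignment with validated `$partitions`.
#' @export
set_partitions <- function(aln, partitions) {
  stopifnot(inherits(aln, "dna_alignment"),
            all(c("gene", "start", "end") %in% names(partitions)))
  p <- data.frame(gene = as.character(partitions$gene),
                  start = as.integer(partitions$start),
                  end = as.integer(partitions$end),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$gene))
    stop("duplicate partition name(s): ",
         paste(unique(p$gene[duplicated(p$gene)]), collapse = ", "))
  if (any(p$start < 1L) || any(p$end > ncol(aln$seq)) || any(p$start > p$end))
    stop("partition range outside [1, ", ncol(aln$seq), "]")
  aln$partitions <- p
  aln
}

#' Read a FASTA alignment
#'
#' Strict reader for aligned FASTA: all records must have the same
#' length. Sequences are upper-cased and RNA `U` is stored as `T`.
#'
#' @param path FASTA file.
#' @param partitions Optional partition table or path to a partition file
#'   (see [read_partition_file()]).
#' @return A [dna_alignment()].
#' @export
read_fasta_alignment <- function(path, partitions = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not FASTA: first non-blank line is not a header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1L))
  if (length(seqs) != length(ids)) stop("FASTA record with no sequence lines")
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: record '", ids[which(lens != lens[1L])[1L]],
         "' has length ", lens[which(lens != lens[1L])[1L]],
         " but '", ids[1L], "' has ", lens[1L])
  aln <- dna_alignment(seqs)
  if (!is.null(partitions)) {
    if (is.character(partitions)) partitions <- read_partition_file(partitions)
    aln <- set_partitions(aln, partitions)
  }
  aln
}

#' Write an alignment as FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta_alignment <- function(aln, path, width = 80L) {
  stopifnot(inherits(aln, "dna_alignment"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(aln$seq))) {
    s <- paste(aln$seq[i, ], collapse = "")
    writeLines(c(paste0(">", rownames(aln$seq)[i]),
                 substring(s, seq(1L, nchar(s), width),
                           pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read a partition table
#'
#' Accepts either RAxML-style partition files (`DNA, ND2 = 1-1059`) or a
#' CSV with columns `gene`, `start`, `end`.
#'
#' @param path Partition file.
#' @return `data.frame` with columns `gene`, `start`, `end`.
#' @export
read_partition_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl(",", lines[1L]) && grepl("=", lines[1L])) {
    m <- regmatches(lines,
                    regexec("^\\s*\\w+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
                            lines))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad)) stop("unparseable partition line: '", lines[bad][1L], "'")
    data.frame(gene = vapply(m, `[`, "", 2L),
               start = as.integer(vapply(m, `[`, "", 3L)),
               end = as.integer(vapply(m, `[`, "", 4L)),
               stringsAsFactors = FALSE)
  } else {
    p <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "start", "end") %in% names(p)))
    p[, c("gene", "start", "end")]
  }
}

#' Write a partition table in RAxML format
#'
#' @param partitions `data.frame` with `gene`, `start`, `end`.
#' @param path Output file.
#' @export
write_partition_file <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$gene,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' Extract the columns of one partition
#'
#' @param aln A `dna_alignment` with a partition table.
#' @param gene Partition name.
#' @return A `dna_alignment` restricted to that gene's columns.
#' @export
extract_partition <- function(aln, gene) {
  stopifnot(inherits(aln, "dna_alignment"), !is.null(aln$partitions))
  row <- aln$partitions[aln$partitions$gene == gene, ]
  if (!nrow(row)) stop("no such partition: ", gene)
  dna_alignment(aln$seq[, row$start:row$end, drop = FALSE])
}

# columns selected by an optional 1-based inclusive range
.range_cols <- function(aln, range) {
  if (is.null(range)) return(seq_len(ncol(aln$seq)))
  stopifnot(length(range) == 2L, range[1L] >= 1L, range[2L] <= ncol(aln$seq),
            range[1L] <= range[2L])
  seq.int(range[1L], range[2L])
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct
#' unambiguous nucleotide states (A, C, G, T) each occur in at least two
#' sequences. Gaps and IUPAC ambiguity codes are treated as missing data
#' and never counted as states.
#'
#' @param aln A `dna_alignment`.
#' @param range Optional 1-based inclusive column range `c(from, to)`.
#' @return Integer count of informative columns.
#' @export
count_parsimony_informative <- function(aln, range = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  cols <- .range_cols(aln, range)
  m <- aln$seq[, cols, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  n_inf <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- tabulate(match(m[, j], bases), nbins = 4L)
    if (sum(tab >= 2L) >= 2L) n_inf <- n_inf + 1L
  }
  n_inf
}

#' Standardized information content (SIC)
#'
#' Parsimony-informative sites per kilobase of alignment:
#' `1000 * PI / length`, conventionally reported to 2 decimals.
#'
#' @param aln A `dna_alignment`.
#' @param range Optional column range, as in
#'   [count_parsimony_informative()].
#' @param digits Decimals for rounding (default 2; `NA` = no rounding).
#' @return SIC value.
#' @export
sic <- function(aln, range = NULL, digits = 2L) {
  cols <- .range_cols(aln, range)
  if (!length(cols)) stop("zero-length range")
  sic_value(count_parsimony_informative(aln, range), length(cols),
            digits = digits)
}

#' @rdname sic
#' @param pi_sites Number of parsimony-informative sites.
#' @param length_bp Alignment length in bp.
#' @export
sic_value <- function(pi_sites, length_bp, digits = 2L) {
  if (length_bp <= 0) stop("alignment length must be positive")
  x <- 1000 * pi_sites / length_bp
  if (is.na(digits)) x else round(x, digits)
}
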