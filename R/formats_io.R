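# Standard-format I/O. FASTA goes through Biostrings; SAM text and
# show-coords tables are parsed into plain data.frames with one internal
# coordinate convention (0-based half-open). Conversions happen only here.

#' Construct a contig set
#'
#' A contig set is an ordered named collection of nucleotide sequences,
#' the in-memory form of one input assembly.
#'
#' @param sequences named character vector of uppercase sequences.
#' @param set_id short label for the assembly.
#' @return an object of class `contig_set`.
#' @export
contig_set <- function(sequences, set_id = "set") {
  if (!length(sequences)) stop("a contig set must contain at least one contig")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate contig id(s): ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  sequences <- chartr("U", "T", sequences)
  sequences[] <- gsub("[^ACGTN]", "N", sequences)
  if (any(nchar(sequences) == 0)) {
    stop("empty sequence for contig(s): ",
         paste(names(sequences)[nchar(sequences) == 0], collapse = ", "))
  }
  structure(list(set_id = set_id, contigs = sequences), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set '%s'> %d contigs, %s bp total, N50 %s\n",
              x$set_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              format(n50(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Lengths of the contigs in a set
#' @param set a `contig_set`.
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(set) {
  stats::setNames(nchar(set$contigs), names(set$contigs))
}

#' Read a FASTA file into a contig set
#'
#' Lowercase is mapped to uppercase and characters outside A,C,G,T,N to N.
#'
#' @param path FASTA file path.
#' @param set_id label for the set; defaults to the file name without extension.
#' @return a `contig_set`.
#' @export
read_fasta <- function(path, set_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1L], "' in ", path)
  }
  if (is.null(set_id)) set_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  contig_set(stats::setNames(as.character(ss), ids), set_id = set_id)
}

#' Write a contig set to FASTA
#'
#' @param set a `contig_set`.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, the path.
#' @export
write_fasta <- function(set, path, width = 70L) {
  stopifnot(inherits(set, "contig_set"), width >= 1L)
  if (!length(set$contigs)) stop("refusing to write an empty contig set")
  ss <- Biostrings::DNAStringSet(set$contigs)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Parse mapped records from a SAM file
#'
#' Unmapped records are skipped; the 1-based POS becomes a 0-based `start`.
#' Hard clips are ignored. `ref_span` is the reference-consuming CIGAR length
#' and `mean_bq` the mean base quality (Phred) of the read.
#'
#' @param path SAM file path.
#' @return data.frame of alignment records, one row per mapped record, in
#'   input order: read_id, mate (1/2), contig_id, start, cigar, mapq,
#'   ref_span, query_len, mean_bq, is_reverse, mate_contig_id (NA when the
#'   mate is unmapped or absent).
#' @export
parse_sam_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  recs <- lines[body]
  recs <- recs[nzchar(recs)]
  if (!length(recs)) return(empty_alignments())
  f <- strsplit(recs, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    stop("SAM record with fewer than 11 fields at line ", body[which(nf < 11L)[1L]])
  }
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  lineno <- body[nzchar(lines[body])][mapped]
  if (!length(f)) return(empty_alignments())
  read_id <- vapply(f, `[[`, "", 1L)
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  mapq <- as.integer(vapply(f, `[[`, "", 5L))
  cigar <- vapply(f, `[[`, "", 6L)
  rnext <- vapply(f, `[[`, "", 7L)
  seqs <- vapply(f, `[[`, "", 10L)
  quals <- vapply(f, `[[`, "", 11L)
  sp <- cigar_spans(cigar)
  seq_len_known <- seqs != "*"
  mism <- which(seq_len_known & nchar(seqs) != sp$query_len)
  if (length(mism)) {
    stop("CIGAR/sequence length mismatch at SAM line ", lineno[mism[1L]],
         " (read ", read_id[mism[1L]], ")")
  }
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  mate_unmapped <- bitwAnd(flag, 8L) > 0L | rnext == "*"
  mate_contig <- ifelse(mate_unmapped, NA_character_,
                        ifelse(rnext == "=", rname, rnext))
  mean_bq <- vapply(quals, function(q) {
    if (q == "*") return(NA_real_)
    mean(as.integer(charToRaw(q)) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(
    read_id = read_id, mate = mate, contig_id = rname,
    start = pos - 1L, cigar = cigar, mapq = mapq,
    ref_span = sp$ref_span, query_len = sp$query_len,
    mean_bq = mean_bq, is_reverse = bitwAnd(flag, 16L) > 0L,
    mate_contig_id = mate_contig, stringsAsFactors = FALSE
  )
}

empty_alignments <- function() {
  data.frame(read_id = character(0), mate = integer(0), contig_id = character(0),
             start = integer(0), cigar = character(0), mapq = integer(0),
             ref_span = integer(0), query_len = integer(0), mean_bq = numeric(0),
             is_reverse = logical(0), mate_contig_id = character(0),
             stringsAsFactors = FALSE)
}

#' Validate alignment records against a contig set
#'
#' Checks that every record's reference span lies within its contig.
#'
#' @param records alignment records.
#' @param set a `contig_set`.
#' @return invisibly TRUE; errors on the first violation.
#' @export
validate_alignments <- function(records, set) {
  len <- contig_lengths(set)
  unknown <- setdiff(records$contig_id, names(len))
  if (length(unknown)) stop("alignment to unknown contig: ", unknown[1L])
  over <- which(records$start + records$ref_span > len[records$contig_id] |
                  records$start < 0L)
  if (length(over)) {
    stop("alignment of read ", records$read_id[over[1L]],
         " exceeds bounds of contig ", records$contig_id[over[1L]])
  }
  invisible(TRUE)
}

#' Parse a show-coords style table of block matches
#'
#' Expects the MUMmer `show-coords -T` layout: tab/space separated rows with
#' reference start/end, query start/end (1-based inclusive), ..., percent
#' identity, and the two sequence names as the last two columns. Here the
#' first coordinate pair is taken as set O and the second as set R. Reversed
#' intervals (end < start) yield `same_strand = FALSE` with normalized
#' ascending 0-based half-open coordinates.
#'
#' @param path table path.
#' @return data.frame of block matches: o_contig, o_start, o_end, r_contig,
#'   r_start, r_end, same_strand, identity (fraction in 0..1).
#' @export
parse_coords_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # skip any header/separator lines that do not start with a number
  lines <- lines[grepl("^[0-9]", lines)]
  if (!length(lines)) {
    warning("empty coords table: ", path)
    return(empty_block_matches())
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(tok) < 7L) stop("unparseable coords row ", i, ": ", lines[i])
    nums <- suppressWarnings(as.numeric(tok[1:4]))
    if (any(is.na(nums))) stop("unparseable coordinates in coords row ", i)
    idnum <- suppressWarnings(as.numeric(tok))
    pid_idx <- utils::tail(which(!is.na(idnum)), 1L)
    identity <- idnum[pid_idx] / 100
    ids <- tok[(length(tok) - 1L):length(tok)]
    o <- sort(nums[1:2]); r <- nums[3:4]
    same <- r[2L] >= r[1L]
    r <- sort(r)
    out[[i]] <- data.frame(
      o_contig = ids[1L], o_start = o[1L] - 1, o_end = o[2L],
      r_contig = ids[2L], r_start = r[1L] - 1, r_end = r[2L],
      same_strand = same, identity = identity, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

empty_block_matches <- function() {
  data.frame(o_contig = character(0), o_start = numeric(0), o_end = numeric(0),
             r_contig = character(0), r_start = numeric(0), r_end = numeric(0),
             same_strand = logical(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write the adjacency report of a merged assembly
#'
#' Tab-separated: output contig id, ordered signed block ids, and the source
#' of each emitted segment.
#'
#' @param merged a `merged_assembly` (see [merge_pair()]).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_adjacency_report <- function(merged, path) {
  chains <- vapply(merged$chains, function(ch) paste(ch$blocks, collapse = ","),
                   character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("contig_id\tblocks\tsegments", con)
  for (i in seq_along(merged$chains)) {
    prov <- merged$provenance[merged$provenance$out_contig ==
                               merged$chains[[i]]$id, , drop = FALSE]
    seg <- paste(sprintf("%s:%s:%d-%d", prov$source_set, prov$source_contig,
                         prov$source_start, prov$source_end), collapse = ";")
    writeLines(paste(merged$chains[[i]]$id, chains[i], seg, sep = "\t"), con)
  }
  invisible(path)
}
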