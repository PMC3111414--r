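#' Extract promoter sequences from a genome and annotation
#'
#' Takes the `promoter_len` bases immediately upstream of each annotated
#' gene start: for a + strand gene starting at 1-based position s, bases
#' `[max(1, s - promoter_len), s - 1]` of the forward strand; for a - strand
#' gene ending at e, bases `[e + 1, e + promoter_len]` reverse-complemented.
#' Promoters truncated at contig edges are kept and flagged; genes on
#' contigs absent from the FASTA are skipped with a warning, and genes with
#' a zero-length promoter (gene starting at the contig edge) are dropped
#' with a warning.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param annotation A `GenomicRanges::GRanges` (with `type` and `ID`
#'   metadata as in GFF3), a path to a GFF3 file, or a data.frame with
#'   columns `gene_id`, `seqid`, `start`, `end`, `strand`.
#' @param promoter_len Promoter length in bases (default 500).
#' @return A list of class `promoter_set`: `sequences` (named character
#'   vector, uppercase), `truncated` (logical, promoters shorter than
#'   `promoter_len`), `promoter_len`.
#' @export
extract_promoters <- function(genome, annotation, promoter_len = 500) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # first word of the FASTA header is the contig name
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- .as_gene_table(annotation)
  if (promoter_len < 1) stop("promoter_len must be positive")

  known <- ann$seqid %in% names(genome)
  if (!all(known)) {
    warning("skipping ", sum(!known), " gene(s) on contigs absent from FASTA")
    ann <- ann[known, , drop = FALSE]
  }
  clen <- Biostrings::width(genome)[match(ann$seqid, names(genome))]
  plus <- ann$strand != "-"
  from <- ifelse(plus, pmax(1L, ann$start - promoter_len), ann$end + 1L)
  to <- ifelse(plus, ann$start - 1L, pmin(clen, ann$end + promoter_len))
  ok <- to >= from & from <= clen & to >= 1L
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " gene(s) with zero-length promoter")
    ann <- ann[ok, , drop = FALSE]; from <- from[ok]; to <- to[ok]
    plus <- plus[ok]
  }
  segs <- Biostrings::subseq(genome[ann$seqid], start = from, end = to)
  segs[!plus] <- Biostrings::reverseComplement(segs[!plus])
  seqs <- toupper(as.character(segs))
  names(seqs) <- ann$gene_id
  structure(list(sequences = seqs,
                 truncated = nchar(seqs) < promoter_len,
                 promoter_len = promoter_len),
            class = "promoter_set")
}

.as_gene_table <- function(annotation) {
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gff3")
  if (inherits(annotation, "GRanges")) {
    gr <- annotation
    if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      as.character(seq_along(gr))
    annotation <- data.frame(
      gene_id = ids,
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "seqid", "start", "end", "strand") %in%
                  names(annotation)))
  if (anyDuplicated(annotation$gene_id)) stop("duplicate gene IDs")
  annotation
}

#' Promoter set from a named character vector
#'
#' Convenience constructor for promoter sets built in code (e.g. by
#' [simulate_promoters()]) or read from FASTA.
#'
#' @param sequences Named character vector of uppercase DNA sequences, or a
#'   path to a FASTA file.
#' @param promoter_len Nominal promoter length (default: longest sequence).
#' @return A `promoter_set`.
#' @export
promoter_set <- function(sequences, promoter_len = NULL) {
  if (length(sequences) == 1L && is.null(names(sequences)) &&
      file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- stats::setNames(toupper(as.character(ss)),
                                 sub("\\s.*$", "", names(ss)))
  }
  sequences <- toupper(sequences)
  if (length(sequences) > 0 && is.null(names(sequences)))
    stop("sequences must be named by gene ID")
  if (any(grepl("[^ACGTN]", sequences))) stop("sequences must be A/C/G/T/N")
  if (anyDuplicated(names(sequences))) stop("duplicate gene IDs")
  if (is.null(promoter_len))
    promoter_len <- if (length(sequences)) max(nchar(sequences)) else 0L
  structure(list(sequences = sequences,
                 truncated = nchar(sequences) < promoter_len,
                 promoter_len = promoter_len),
            class = "promoter_set")
}

#' Does a promoter contain a word?
#'
#' Substring containment of a DNA word, by default on either strand (the
#' word or its reverse complement). `N` bases never match.
#'
#' @param promoters A `promoter_set`, or a character vector of sequences.
#' @param word DNA word of length 3-8 (A/C/G/T only).
#' @param both_strands Also match the reverse complement (default TRUE).
#' @return Logical vector, one element per promoter.
#' @export
contains_word <- function(promoters, word, both_strands = TRUE) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$sequences
          else promoters
  word <- toupper(word)
  if (grepl("[^ACGT]", word)) stop("word must contain only A/C/G/T")
  if (nchar(word) < 3 || nchar(word) > 8) stop("word length must be 3-8")
  if (length(seqs) == 0) return(logical(0))
  ss <- Biostrings::DNAStringSet(seqs)
  hit <- Biostrings::vcountPattern(word, ss, fixed = TRUE) > 0
  if (both_strands && .revcomp(word) != word)
    hit <- hit | Biostrings::vcountPattern(.revcomp(word), ss,
                                           fixed = TRUE) > 0
  stats::setNames(hit, names(seqs))
}
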