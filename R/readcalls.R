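## From alignments (or a pre-extracted read-call table) to per-bin sets of
## binary CpG methylation vectors on a fixed 300 bp tiling.
##
## Conventions: R objects follow GRanges (1-based, closed); all files are
## 0-based half-open (BED, chrom sizes, and the read-call table's
## cpg_positions column, which holds the 0-based coordinate of the C of
## each CpG on the plus strand).

#' Read a two-column chromosome-sizes file
#'
#' @param path Tab-separated file with columns chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Tile the genome into fixed-width bins
#'
#' Produces non-overlapping consecutive bins covering every chromosome
#' exactly; a shorter-than-\code{binSize} terminal bin is kept and flagged
#' \code{short}. With \code{step < binSize} a sliding tiling is produced
#' instead.
#'
#' @param chromSizes Named vector of chromosome lengths (see
#'   \code{\link{readChromSizes}}).
#' @param binSize Bin width in bp (default 300).
#' @param step Distance between bin starts; defaults to \code{binSize}
#'   (non-overlapping tiling).
#' @return A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{bin_id} and \code{short}.
#' @examples
#' tileBins(c(chr1 = 900), 300)    # 3 bins
#' tileBins(c(chr1 = 1000), 300)   # 4 bins, last one short
#' @export
tileBins <- function(chromSizes, binSize = 300L, step = binSize) {
  if (length(chromSizes) == 0)
    stop("'chromSizes' is empty: no chromosomes to tile")
  stopifnot(binSize > 0, step > 0, !is.null(names(chromSizes)))
  sl <- stats::setNames(as.integer(chromSizes), names(chromSizes))
  if (step == binSize) {
    bins <- GenomicRanges::tileGenome(sl, tilewidth = binSize,
                                      cut.last.tile.in.chrom = TRUE)
  } else {
    whole <- GenomicRanges::GRanges(
      names(sl), IRanges::IRanges(1L, unname(sl)), seqlengths = sl)
    bins <- unlist(GenomicRanges::slidingWindows(whole, width = binSize,
                                                 step = step))
  }
  bins$short <- GenomicRanges::width(bins) < binSize
  bins$bin_id <- sprintf("%s:%d-%d", GenomeInfoDb::seqnames(bins),
                         GenomicRanges::start(bins),
                         GenomicRanges::end(bins))
  names(bins) <- NULL
  bins
}

.new_read_frame <- function(read_id, chrom, start, end, strand, pos, calls,
                            qc = list()) {
  df <- S4Vectors::DataFrame(
    read_id = read_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand,
    pos = IRanges::IntegerList(pos), calls = IRanges::IntegerList(calls))
  S4Vectors::metadata(df) <- list(qc = qc)
  df
}

#' Load a read-call table
#'
#' Reads the bespoke TSV of per-read CpG methylation calls: one row per
#' mapped read with columns \code{read_id}, \code{chrom},
#' \code{cpg_positions} (comma-separated 0-based coordinates of the CpG C
#' on the plus strand) and \code{calls} (a string of 0/1 characters, one
#' per position). Optional columns \code{start}, \code{end} (0-based
#' half-open read coordinates) and \code{strand} sharpen duplicate
#' detection; when absent they are derived from the CpG span and the
#' strand is set to \code{"*"}.
#'
#' @param path Path to the TSV.
#' @return A \link[S4Vectors]{DataFrame} with one row per read and columns
#'   \code{read_id}, \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{pos} (1-based CpG C positions, an \code{IntegerList}) and
#'   \code{calls} (an \code{IntegerList} of 0/1).
#' @export
loadReadCallTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("read_id", "chrom", "cpg_positions", "calls")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("read-call table lacks column(s): ", paste(miss, collapse = ", "))
  pos <- strsplit(df$cpg_positions, ",", fixed = TRUE)
  calls <- strsplit(df$calls, "", fixed = TRUE)
  bad_len <- which(lengths(pos) != lengths(calls))
  if (length(bad_len))
    stop(sprintf("line %d: %d CpG positions but %d calls",
                 bad_len[1] + 1L, lengths(pos)[bad_len[1]],
                 lengths(calls)[bad_len[1]]))
  bad_call <- which(!vapply(calls, function(x) all(x %in% c("0", "1")),
                            logical(1)))
  if (length(bad_call))
    stop(sprintf("line %d: non-binary methylation call", bad_call[1] + 1L))
  pos <- lapply(pos, function(p) as.integer(p) + 1L)  # 0-based -> 1-based
  bad_ord <- which(!vapply(pos, function(p) {
    length(p) >= 1L && all(diff(p) > 0)
  }, logical(1)))
  if (length(bad_ord))
    stop(sprintf("line %d: CpG positions must be strictly increasing",
                 bad_ord[1] + 1L))
  calls <- lapply(calls, as.integer)
  first <- vapply(pos, `[`, integer(1), 1L)
  last <- vapply(pos, function(p) p[length(p)], integer(1))
  start <- if ("start" %in% colnames(df)) as.integer(df$start) + 1L else first
  end <- if ("end" %in% colnames(df)) as.integer(df$end) else last + 1L
  strand <- if ("strand" %in% colnames(df)) df$strand
            else rep("*", nrow(df))
  .new_read_frame(df$read_id, df$chrom, start, end, strand, pos, calls,
                  qc = list(reads_seen = nrow(df)))
}

#' Write a read-call table
#'
#' Inverse of \code{\link{loadReadCallTable}}; positions are written
#' 0-based.
#'
#' @param reads Read \code{DataFrame} as produced by
#'   \code{\link{loadReadCallTable}} or \code{\link{sampleReads}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeReadCallTable <- function(reads, path) {
  out <- data.frame(
    read_id = reads$read_id, chrom = reads$chrom,
    start = reads$start - 1L, end = reads$end, strand = reads$strand,
    cpg_positions = vapply(as.list(reads$pos), function(p)
      paste(p - 1L, collapse = ","), character(1)),
    calls = vapply(as.list(reads$calls), paste, character(1), collapse = ""))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cpg_sites <- function(ref) {
  lapply(ref, function(s) Biostrings::start(Biostrings::matchPattern("CG", s)))
}

#' Extract binary CpG methylation vectors from bisulfite alignments
#'
#' For each aligned read, emits one binary call per reference CpG the read
#' fully covers. Plus-strand reads are assessed at the C of the CpG (C =
#' methylated, T = unmethylated after bisulfite conversion); minus-strand
#' reads at the G (G = methylated, A = unmethylated). Both strands are
#' mapped onto the plus-strand C coordinate. Ambiguous bases (neither of
#' the two expected letters at the site) are dropped from the vector, and
#' reads left with zero resolvable CpGs are discarded (counted in QC).
#' Only simple ungapped alignments (CIGAR \code{<n>M}) are used; others are
#' skipped with a counter, as are unmapped reads.
#'
#' @param samPath Path to a SAM (or BAM) file of bisulfite alignments.
#' @param fastaPath Path to the reference FASTA the reads were mapped to.
#' @return A read \code{DataFrame} as from \code{\link{loadReadCallTable}},
#'   with QC counters in \code{S4Vectors::metadata(.)$qc} and the
#'   per-chromosome reference CpG positions in
#'   \code{metadata(.)$cpg_sites}.
#' @export
extractReadVectors <- function(samPath, fastaPath) {
  ref <- Biostrings::readDNAStringSet(fastaPath)
  names(ref) <- sub("\\s.*$", "", names(ref))
  sites <- .cpg_sites(ref)
  bam <- samPath
  if (grepl("\\.sam$", samPath, ignore.case = TRUE))
    bam <- Rsamtools::asBam(samPath, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  qc <- list(reads_seen = length(b$qname), unmapped = 0L,
             complex_cigar = 0L, zero_cpg = 0L)
  mapped <- !bitwAnd(b$flag, 4L)
  qc$unmapped <- sum(!mapped)
  chroms <- as.character(b$rname)
  bad_chrom <- unique(chroms[mapped & !(chroms %in% names(ref))])
  if (length(bad_chrom))
    stop("alignment chromosome(s) absent from reference: ",
         paste(bad_chrom, collapse = ", "))
  simple <- grepl("^\\d+M$", b$cigar)
  qc$complex_cigar <- sum(mapped & !simple)
  use <- which(mapped & simple)
  seqs <- as.character(b$seq)
  out_id <- character(); out_chrom <- character(); out_start <- integer()
  out_end <- integer(); out_strand <- character()
  out_pos <- list(); out_calls <- list()
  for (i in use) {
    chrom <- chroms[i]
    start <- b$pos[i]
    len <- as.integer(sub("M$", "", b$cigar[i]))
    end <- start + len - 1L
    minus <- bitwAnd(b$flag[i], 16L) > 0L
    s <- sites[[chrom]]
    cover <- s[s >= start & s + 1L <= end]  # full CG inside the read
    if (length(cover)) {
      off <- if (minus) cover + 1L - start + 1L else cover - start + 1L
      base <- substring(seqs[i], off, off)
      call <- if (minus) ifelse(base == "G", 1L, ifelse(base == "A", 0L, NA))
              else ifelse(base == "C", 1L, ifelse(base == "T", 0L, NA))
      keep <- !is.na(call)
      cover <- cover[keep]; call <- call[keep]
    } else call <- integer()
    if (!length(cover)) {
      qc$zero_cpg <- qc$zero_cpg + 1L
      next
    }
    out_id <- c(out_id, b$qname[i]); out_chrom <- c(out_chrom, chrom)
    out_start <- c(out_start, start); out_end <- c(out_end, end)
    out_strand <- c(out_strand, if (minus) "-" else "+")
    out_pos[[length(out_pos) + 1L]] <- as.integer(cover)
    out_calls[[length(out_calls) + 1L]] <- as.integer(call)
  }
  df <- .new_read_frame(out_id, out_chrom, out_start, out_end, out_strand,
                        out_pos, out_calls, qc = qc)
  S4Vectors::metadata(df)$cpg_sites <- sites
  df
}

#' Assign reads to bins, clipping calls at bin boundaries
#'
#' A read contributes to every bin it overlaps, using only the CpG calls
#' falling inside that bin; calls outside are clipped (so the multiset of a
#' read's in-bin calls across bins equals its full vector). Duplicate reads
#' (identical chromosome, start, strand and length) are collapsed to one
#' before assignment. Reads overlapping no bin are counted and skipped.
#'
#' @param reads Read \code{DataFrame} (from \code{\link{loadReadCallTable}}
#'   or \code{\link{extractReadVectors}}).
#' @param bins \code{GRanges} tiling from \code{\link{tileBins}}.
#' @param cpgSites Optional per-chromosome list of reference CpG C
#'   positions (1-based), used to count \code{n_cpg} per bin; when absent,
#'   the distinct CpG positions observed in the reads are counted instead.
#' @return A \linkS4class{BinnedReads}.
#' @export
assignReadsToBins <- function(reads, bins, cpgSites = NULL) {
  qc <- S4Vectors::metadata(reads)$qc
  if (is.null(qc)) qc <- list()
  key <- paste(reads$chrom, reads$start, reads$strand,
               reads$end - reads$start + 1L)
  dup <- duplicated(key)
  qc$duplicates_removed <- sum(dup)
  reads <- reads[!dup, ]
  n_read <- nrow(reads)
  plen <- lengths(reads$pos)
  ridx <- rep.int(seq_len(n_read), plen)
  pos <- unlist(as.list(reads$pos), use.names = FALSE)
  call <- unlist(as.list(reads$calls), use.names = FALSE)
  gp <- GenomicRanges::GRanges(rep.int(reads$chrom, plen),
                               IRanges::IRanges(pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(gp, bins, select = "first")
  keep <- !is.na(hit)
  qc$reads_outside_bins <- length(unique(ridx[!keep])) -
    length(intersect(unique(ridx[!keep]), unique(ridx[keep])))
  hit <- hit[keep]; ridx2 <- ridx[keep]; pos2 <- pos[keep]
  call2 <- call[keep]
  read_lists <- rep(list(list(read_id = character(0), M = integer(0),
                              l = integer(0), calls = list(),
                              pos = list())), length(bins))
  if (length(hit)) {
    o <- order(hit, ridx2)
    hit <- hit[o]; ridx2 <- ridx2[o]; pos2 <- pos2[o]; call2 <- call2[o]
    rows_by_bin <- split(seq_along(hit), hit)
    ids <- reads$read_id
    for (bname in names(rows_by_bin)) {
      rows <- rows_by_bin[[bname]]
      f <- factor(ridx2[rows], levels = unique(ridx2[rows]))
      cl <- split(call2[rows], f)
      pl <- split(pos2[rows], f)
      read_lists[[as.integer(bname)]] <- list(
        read_id = ids[as.integer(levels(f))],
        M = vapply(cl, sum, numeric(1), USE.NAMES = FALSE),
        l = unname(lengths(cl)),
        calls = unname(cl), pos = unname(pl))
    }
  }
  bins$coverage <- vapply(read_lists, function(x) length(x$M), integer(1))
  if (!is.null(cpgSites)) {
    sgr <- GenomicRanges::GRanges(
      rep.int(names(cpgSites), lengths(cpgSites)),
      IRanges::IRanges(unlist(cpgSites, use.names = FALSE), width = 1L))
    bins$n_cpg <- GenomicRanges::countOverlaps(bins, sgr)
  } else {
    ncpg <- integer(length(bins))
    obs <- tapply(pos2, hit, function(p) length(unique(p)))
    ncpg[as.integer(names(obs))] <- as.integer(obs)
    bins$n_cpg <- ncpg
  }
  new("BinnedReads", bins = bins, reads = read_lists, qc = qc)
}

#' Keep qualifying bins
#'
#' A qualifying bin has more than \code{minCpG} reference CpGs (strict) and
#' at least \code{minCov} reads. Short terminal bins are excluded.
#'
#' @param x A \linkS4class{BinnedReads}.
#' @param minCpG CpG-count threshold (a bin must exceed it; default 10).
#' @param minCov Minimum read count (default 10).
#' @return The subsetted \linkS4class{BinnedReads}.
#' @export
qualifyingBins <- function(x, minCpG = 10L, minCov = 10L) {
  keep <- !x@bins$short & x@bins$n_cpg > minCpG & x@bins$coverage >= minCov
  new("BinnedReads", bins = x@bins[keep], reads = x@reads[keep],
      qc = c(x@qc, list(qualifying = sum(keep), non_qualifying = sum(!keep))))
}
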