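## Synthetic two-component bisulfite read mixtures with known truth.
##
## Emulates mixing reads from two pure cell populations ("normal", the
## minor component at fraction alpha1, and "tumor") at a chosen fold
## coverage: per bin the two populations contribute reads in proportion to
## their fractions (Poisson sampling), each read covers the CpGs inside a
## 70-100 bp window, and its binary calls follow the bin's per-population
## methylation level -- by default concordantly (all-or-none per read, the
## dominant pattern in pure populations), optionally as independent
## per-CpG Bernoulli draws (the mixture model's own assumption).

#' Simulation configuration
#'
#' @param nBins Number of 300 bp bins to simulate (default 2000).
#' @param binSize Bin width in bp.
#' @param alpha1 True minor ("normal") fraction in \eqn{[0, 0.5]}.
#' @param coverage Mean fold coverage (default 20); reads per bin are
#'   Poisson with mean \code{coverage * binSize / mean(readLenRange)}.
#' @param readLenRange Read length range in bp (default 70--100).
#' @param cpgRange CpGs per qualifying-density bin (default 15--25).
#' @param fracLowCpG Fraction of bins given few CpGs (below the qualifying
#'   threshold), default 0.
#' @param lowCpGRange CpG count range for low-CpG bins.
#' @param fracDifferential Fraction of bins truly differentially
#'   methylated (default 0.2).
#' @param mode \code{"dichotomous"} (levels in \{0, 1\}, the pattern seen
#'   in real pure populations) or \code{"intermediate"} (continuous
#'   levels; differential bins still differ by > 0.5).
#' @param concordant Whether a read's calls are all-or-none with
#'   probability \code{m} (default) or independent Bernoulli(\code{m}) per
#'   CpG.
#' @param conversionError Rate at which methylated calls are flipped to
#'   unmethylated (default 0.005).
#' @param truthThreshold Difference defining a true DMB (default 0.5).
#' @param nASM Number of allele-specific-methylation confounder bins:
#'   their normal-component reads are 50/50 fully methylated/unmethylated.
#' @param nCNA Number of tumor-amplified bins; their tumor read counts are
#'   multiplied by \code{cnaMultiplier}.
#' @param cnaMultiplier Coverage multiplier in CNA bins (default 3).
#' @param chrom Chromosome name used for the synthetic genome.
#' @param seed Seed applied by \code{\link{makeGenome}} (optional).
#' @return Named list with class \code{"SimConfig"}.
#' @export
simConfig <- function(nBins = 2000L, binSize = 300L, alpha1 = 0.3,
                      coverage = 20, readLenRange = c(70L, 100L),
                      cpgRange = c(15L, 25L), fracLowCpG = 0,
                      lowCpGRange = c(4L, 8L), fracDifferential = 0.2,
                      mode = c("dichotomous", "intermediate"),
                      concordant = TRUE, conversionError = 0.005,
                      truthThreshold = 0.5, nASM = 0L, nCNA = 0L,
                      cnaMultiplier = 3, chrom = "simChr1", seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha1 >= 0, alpha1 <= 0.5, coverage > 0,
            conversionError >= 0, conversionError <= 1,
            fracDifferential >= 0, fracDifferential <= 1)
  cfg <- list(nBins = as.integer(nBins), binSize = as.integer(binSize),
              alpha1 = alpha1, coverage = coverage,
              readLenRange = as.integer(readLenRange),
              cpgRange = as.integer(cpgRange), fracLowCpG = fracLowCpG,
              lowCpGRange = as.integer(lowCpGRange),
              fracDifferential = fracDifferential, mode = mode,
              concordant = concordant, conversionError = conversionError,
              truthThreshold = truthThreshold, nASM = as.integer(nASM),
              nCNA = as.integer(nCNA), cnaMultiplier = cnaMultiplier,
              chrom = chrom, seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

#' Lay out a synthetic genome with per-bin methylation truth
#'
#' Draws per-bin CpG positions (spacing >= 2 bp so CpG dinucleotides never
#' overlap) and the true per-population methylation pair; marks true DMBs,
#' ASM bins and CNA bins. Reproducible from \code{config$seed}.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list with class \code{"SyntheticGenome"}: \code{bins} (a
#'   \code{GRanges} with truth metadata), \code{cpg_pos} (per-bin 1-based C
#'   positions), \code{chromSizes}, \code{cnaRegions}, \code{asmRegions}
#'   and \code{config}.
#' @export
makeGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$nBins
  sizes <- stats::setNames(n * config$binSize, config$chrom)
  bins <- tileBins(sizes, config$binSize)
  low <- stats::runif(n) < config$fracLowCpG
  ncpg <- ifelse(low,
                 sample(config$lowCpGRange[1]:config$lowCpGRange[2], n,
                        replace = TRUE),
                 sample(config$cpgRange[1]:config$cpgRange[2], n,
                        replace = TRUE))
  cpg_pos <- lapply(seq_len(n), function(i) {
    cand <- seq(GenomicRanges::start(bins)[i],
                GenomicRanges::end(bins)[i] - 1L, by = 2L)
    sort(sample(cand, min(ncpg[i], length(cand))))
  })
  is_diff <- stats::runif(n) < config$fracDifferential
  swap <- stats::runif(n) < 0.5
  if (config$mode == "dichotomous") {
    m_shared <- stats::rbinom(n, 1L, 0.5)
    m_lo <- ifelse(is_diff, 0, m_shared)
    m_hi <- ifelse(is_diff, 1, m_shared)
  } else {
    m_shared <- stats::runif(n)
    m_lo <- ifelse(is_diff, stats::runif(n, 0, 0.35), m_shared)
    m_hi <- ifelse(is_diff, pmin(1, m_lo + stats::runif(n, 0.55, 0.65)),
                   m_shared)
  }
  m_normal <- ifelse(swap, m_hi, m_lo)
  m_tumor <- ifelse(swap, m_lo, m_hi)
  is_asm <- rep(FALSE, n)
  if (config$nASM > 0) {
    cand <- which(!is_diff)
    is_asm[sample(cand, min(config$nASM, length(cand)))] <- TRUE
  }
  cna_mult <- rep(1, n)
  if (config$nCNA > 0)
    cna_mult[sample.int(n, min(config$nCNA, n))] <- config$cnaMultiplier
  bins$n_cpg_true <- lengths(cpg_pos)
  bins$m_normal <- m_normal
  bins$m_tumor <- m_tumor
  bins$is_dmb <- abs(m_normal - m_tumor) > config$truthThreshold
  bins$is_asm <- is_asm
  bins$cna_mult <- cna_mult
  g <- list(bins = bins, cpg_pos = cpg_pos, chromSizes = sizes,
            cnaRegions = GenomicRanges::reduce(bins[cna_mult > 1]),
            asmRegions = GenomicRanges::reduce(bins[is_asm]),
            config = config)
  class(g) <- "SyntheticGenome"
  g
}

#' Sample bisulfite reads from a synthetic genome
#'
#' Per bin, normal and tumor read counts are Poisson with means
#' \eqn{\lambda \alpha_1} and \eqn{\lambda (1-\alpha_1) c} (with
#' \eqn{\lambda} the expected reads per bin and \eqn{c} the bin's CNA
#' multiplier), so local mixing follows the global fractions subject to
#' sampling noise. Calls follow the configured read model; methylated
#' calls are flipped to unmethylated at \code{conversionError}. Reads
#' covering no CpG are dropped (counted). Uses the current RNG state;
#' run \code{\link{makeGenome}} (which seeds) then this for reproducible
#' pairs.
#'
#' @param genome A \code{"SyntheticGenome"} from \code{\link{makeGenome}}.
#' @param config Defaults to \code{genome$config}.
#' @return List with \code{reads} (read \code{DataFrame} as in
#'   \code{\link{loadReadCallTable}}, plus a truth \code{component}
#'   column) and \code{truth} (per-bin data.frame with \code{bin_id},
#'   coordinates, \code{m_normal}, \code{m_tumor}, \code{is_dmb},
#'   \code{is_asm}, \code{cna_mult}).
#' @export
sampleReads <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  bins <- genome$bins
  n <- length(bins)
  lambda <- config$coverage * config$binSize / mean(config$readLenRange)
  nn <- stats::rpois(n, lambda * config$alpha1)
  nt <- stats::rpois(n, lambda * (1 - config$alpha1) * bins$cna_mult)
  acc <- vector("list", n)
  zero_cpg <- 0L
  bstart <- GenomicRanges::start(bins)
  bend <- GenomicRanges::end(bins)
  for (i in seq_len(n)) {
    nr <- nn[i] + nt[i]
    if (nr == 0) next
    comp <- rep(c("normal", "tumor"), c(nn[i], nt[i]))
    len <- sample(config$readLenRange[1]:config$readLenRange[2], nr,
                  replace = TRUE)
    len <- pmin(len, config$binSize)
    rstart <- bstart[i] +
      floor(stats::runif(nr) * (config$binSize - len + 1))
    cpgs <- genome$cpg_pos[[i]]
    lo <- findInterval(rstart - 1L, cpgs) + 1L
    hi <- findInterval(rstart + len - 2L, cpgs)  # needs C and G inside
    k <- pmax(0L, hi - lo + 1L)
    zero_cpg <- zero_cpg + sum(k == 0)
    keep <- k > 0
    if (!any(keep)) next
    comp <- comp[keep]; len <- len[keep]; rstart <- rstart[keep]
    lo <- lo[keep]; k <- k[keep]
    m_read <- ifelse(comp == "normal", bins$m_normal[i], bins$m_tumor[i])
    if (bins$is_asm[i]) {
      asm_allele <- stats::rbinom(length(comp), 1L, 0.5)
      m_read[comp == "normal"] <- asm_allele[comp == "normal"]
    }
    if (config$concordant) {
      state <- stats::rbinom(length(comp), 1L, m_read)
      calls <- rep.int(state, k)
    } else {
      calls <- stats::rbinom(sum(k), 1L, rep.int(m_read, k))
    }
    if (config$conversionError > 0) {
      ones <- which(calls == 1L)
      flip <- ones[stats::runif(length(ones)) < config$conversionError]
      calls[flip] <- 0L
    }
    pos <- cpgs[sequence(k, from = lo)]
    acc[[i]] <- list(n = length(comp), comp = comp, start = rstart,
                     end = rstart + len - 1L, k = k, pos = pos,
                     calls = calls, bin = bins$bin_id[i])
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  n_tot <- sum(vapply(acc, `[[`, integer(1), "n"))
  widths <- unlist(lapply(acc, `[[`, "k"), use.names = FALSE)
  part <- IRanges::PartitioningByWidth(widths)
  reads <- S4Vectors::DataFrame(
    read_id = sprintf("r%08d", seq_len(n_tot)),
    chrom = rep(config$chrom, n_tot),
    start = unlist(lapply(acc, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(acc, `[[`, "end"), use.names = FALSE),
    strand = sample(c("+", "-"), n_tot, replace = TRUE),
    pos = IRanges::relist(
      unlist(lapply(acc, `[[`, "pos"), use.names = FALSE), part),
    calls = IRanges::relist(
      as.integer(unlist(lapply(acc, `[[`, "calls"), use.names = FALSE)),
      part),
    component = unlist(lapply(acc, `[[`, "comp"), use.names = FALSE),
    bin_id = rep(vapply(acc, `[[`, character(1), "bin"),
                 vapply(acc, `[[`, integer(1), "n")))
  S4Vectors::metadata(reads) <- list(qc = list(
    reads_seen = n_tot, zero_cpg_dropped = zero_cpg))
  truth <- data.frame(
    bin_id = bins$bin_id,
    chrom = as.character(GenomeInfoDb::seqnames(bins)),
    start = bstart, end = bend,
    n_cpg = bins$n_cpg_true, m_normal = bins$m_normal,
    m_tumor = bins$m_tumor, is_dmb = bins$is_dmb, is_asm = bins$is_asm,
    cna_mult = bins$cna_mult, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a complete mixture sample
#'
#' Convenience wrapper: seeds from the config, lays out the genome and
#' samples reads. Byte-identical output for identical configs.
#'
#' @param config A \code{\link{simConfig}}.
#' @return List with \code{genome}, \code{reads}, \code{truth}.
#' @export
simulateMixture <- function(config) {
  genome <- makeGenome(config)
  s <- sampleReads(genome, config)
  list(genome = genome, reads = s$reads, truth = s$truth)
}

#' Write a matched SAM + FASTA fixture
#'
#' Renders the synthetic genome as a reference FASTA (background drawn from
#' A/T/G so the only CG dinucleotides are the placed CpG sites) and the
#' sampled reads as ungapped SAM alignments, with bisulfite base coding at
#' the sites: plus-strand reads carry C (methylated) or T at the CpG C,
#' minus-strand reads carry G or A at the CpG G. Non-CpG conversion is not
#' rendered (the extractor only inspects CpG sites).
#'
#' @param genome A \code{"SyntheticGenome"}.
#' @param reads Read \code{DataFrame} from \code{\link{sampleReads}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector with the \code{fasta} and \code{sam}
#'   paths.
#' @export
writeFixtureSAM <- function(genome, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- genome$config$chrom
  len <- unname(genome$chromSizes[chrom])
  chars <- sample(c("A", "T", "G"), len, replace = TRUE)
  sites <- unlist(genome$cpg_pos, use.names = FALSE)
  chars[sites] <- "C"
  chars[sites + 1L] <- "G"
  refstr <- paste(chars, collapse = "")
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(refstr, chrom)), fasta)
  sam <- file.path(dir, "reads.sam")
  pos_l <- as.list(reads$pos)
  calls_l <- as.list(reads$calls)
  lines <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]; e <- reads$end[i]
    seq_chars <- chars[s:e]
    p <- pos_l[[i]]; cl <- calls_l[[i]]
    if (reads$strand[i] == "-") {
      seq_chars[p + 1L - s + 1L] <- ifelse(cl == 1L, "G", "A")
      flag <- 16L
    } else {
      seq_chars[p - s + 1L] <- ifelse(cl == 1L, "C", "T")
      flag <- 0L
    }
    lines[i] <- paste(reads$read_id[i], flag, chrom, s, 60L,
                      paste0(e - s + 1L, "M"), "*", 0L, 0L,
                      paste(seq_chars, collapse = ""), "*", sep = "\t")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
  writeLines(c(hdr, lines), sam)
  c(fasta = fasta, sam = sam)
}

#' Score bin fits against simulator truth
#'
#' Joins fitted bins to the truth table by \code{bin_id} and computes DMB
#' sensitivity and specificity (predicted difference > \code{threshold} vs
#' true DMB label) plus the correlations between fitted and true
#' methylation levels of the minor ("normal") and major ("tumor")
#' components.
#'
#' @param binFits data.frame from \code{\link{fitAllBins}}.
#' @param truth Truth data.frame from \code{\link{sampleReads}}.
#' @param threshold DMB call threshold (default 0.5).
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{cor_minor}, \code{cor_major} and the confusion counts.
#' @export
scoreAgainstTruth <- function(binFits, truth, threshold = 0.5) {
  m <- merge(binFits, truth, by = "bin_id", suffixes = c("", ".truth"))
  pred <- m$diff > threshold
  tp <- sum(pred & m$is_dmb); fn <- sum(!pred & m$is_dmb)
  fp <- sum(pred & !m$is_dmb); tn <- sum(!pred & !m$is_dmb)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    cor_minor = if (nrow(m) > 2 && stats::sd(m$m_normal) > 0)
      stats::cor(m$m1_hat, m$m_normal) else NA_real_,
    cor_major = if (nrow(m) > 2 && stats::sd(m$m_tumor) > 0)
      stats::cor(m$m2_hat, m$m_tumor) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn, n_bins = nrow(m))
}
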