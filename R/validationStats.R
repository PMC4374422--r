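.GT_ALLELES <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"),
                    AO = c("A", "O"), BO = c("B", "O"), OO = c("O", "O"))

# genotypes producible by one allele from each parent (disomic model);
# the null allele O transmits like any other allele
.expectedProgeny <- function(p1, p2) {
  a1 <- .GT_ALLELES[[p1]]; a2 <- .GT_ALLELES[[p2]]
  unique(vapply(seq_len(4), function(i) {
    x <- a1[(i - 1) %/% 2 + 1]; y <- a2[(i - 1) %% 2 + 1]
    paste0(min(x, y), max(x, y))
  }, ""))
}

#' Parent-offspring concordance check under disomic inheritance
#'
#' A progeny call is concordant iff it can be produced by drawing one
#' allele from each parent (null alleles transmit like any allele).
#' Markers with a parental NoCall are flagged discarded. Markers where
#' more than 5% of informative progeny are non-concordant are discarded;
#' markers with a smaller non-zero fraction are retained with the
#' offending progeny calls converted to missing (they are assumed to
#' reflect inadequate genotype designation of individual samples rather
#' than of the parents).
#'
#' @param parent1,parent2 genotype vectors, one entry per marker
#'   (AA/AB/BB/AO/BO/OO/NoCall).
#' @param progeny markers x progeny character matrix.
#' @param max_nonconcordant discard threshold as a fraction of informative
#'   progeny (default 0.05).
#' @return data.frame per marker: n_informative, n_nonconcordant,
#'   fraction, concordant (zero non-concordant), discard, reason; plus
#'   attribute "cleaned" holding the progeny matrix with converted calls.
#' @examples
#' ped <- generatePedigree("AA", "AB", 10, seed = 2)
#' checkConcordance("AA", "AB", ped$progeny)
#' @export
checkConcordance <- function(parent1, parent2, progeny,
                             max_nonconcordant = 0.05) {
  if (is.vector(progeny)) progeny <- matrix(progeny, nrow = 1)
  n <- nrow(progeny)
  if (length(parent1) != n || length(parent2) != n)
    stop("parent vectors and progeny table have different marker counts")
  cleaned <- progeny
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- parent1[i]; p2 <- parent2[i]
    if (p1 == "NoCall" || p2 == "NoCall") {
      out[[i]] <- data.frame(n_informative = 0L, n_nonconcordant = 0L,
                             fraction = NA_real_, concordant = FALSE,
                             discard = TRUE, reason = "parental NoCall")
      next
    }
    exp <- .expectedProgeny(p1, p2)
    inf <- progeny[i, ] != "NoCall"
    bad <- inf & !(progeny[i, ] %in% exp)
    frac <- if (any(inf)) sum(bad) / sum(inf) else 0
    discard <- frac > max_nonconcordant
    if (!discard && any(bad)) cleaned[i, bad] <- "NoCall"
    out[[i]] <- data.frame(
      n_informative = sum(inf), n_nonconcordant = sum(bad),
      fraction = frac, concordant = !any(bad), discard = discard,
      reason = if (discard) sprintf(">%.0f%% non-concordant progeny",
                                    100 * max_nonconcordant) else "")
  }
  res <- do.call(rbind, out)
  rownames(res) <- rownames(progeny)
  attr(res, "cleaned") <- cleaned
  res
}

#' Binomial-test configuration for sequence-derived genotypes
#'
#' @param min_reads minimum read depth for a call (default 20).
#' @param null_maf expected minor-allele frequency under the heterozygous
#'   null (default 1/8, one heterozygous subgenome out of four in an
#'   allo-octoploid).
#' @param alpha significance threshold.
#' @return classed list "binomialTestConfig".
#' @export
binomialTestConfig <- function(min_reads = 20L, null_maf = 1 / 8,
                               alpha = 0.05) {
  stopifnot(null_maf > 0, null_maf < 0.5, alpha > 0, alpha < 1)
  structure(list(min_reads = min_reads, null_maf = null_maf, alpha = alpha),
            class = "binomialTestConfig")
}

#' Sequence-derived genotype from allele read counts
#'
#' With fewer than `min_reads` total reads no call is made. Otherwise the
#' minor (lower-count) allele's count is tested against the one-sided
#' lower binomial tail at the boundary null frequency (default 1/8, the
#' least favourable point of the composite null "minor allele frequency
#' at least 1/8"): `p = P(X <= k_minor | n, 1/8)`. The genotype is
#' homozygous for the major allele when p < alpha, heterozygous
#' otherwise. Ties (k = n/2) give large p and are heterozygous by
#' construction.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorised).
#' @param config a [binomialTestConfig()].
#' @return data.frame(genotype, p_value, major) where genotype is
#'   "hom_major", "het" or "no_call" and major names the major allele
#'   ("ref"/"alt", ties "ref").
#' @examples
#' binomialGenotype(20, 0)  # p = 0.875^20 ~ 0.069 >= 0.05 -> het
#' binomialGenotype(30, 0)  # p ~ 0.018 < 0.05 -> hom_major
#' @export
binomialGenotype <- function(ref_reads, alt_reads,
                             config = binomialTestConfig()) {
  stopifnot(all(ref_reads >= 0), all(alt_reads >= 0))
  n <- ref_reads + alt_reads
  k_minor <- pmin(ref_reads, alt_reads)
  p <- pbinom(k_minor, n, config$null_maf)
  genotype <- ifelse(n < config$min_reads, "no_call",
                     ifelse(p < config$alpha, "hom_major", "het"))
  data.frame(genotype = genotype,
             p_value = ifelse(n < config$min_reads, NA_real_, p),
             major = ifelse(alt_reads > ref_reads, "alt", "ref"),
             stringsAsFactors = FALSE)
}

#' Compare sequence-derived and array-derived genotypes
#'
#' Applies [binomialGenotype()] to per-sample read counts and matches the
#' result against the array call. Comparisons are not possible for array
#' NoCall or null genotypes, for sites with fewer than `min_reads`
#' sequencing reads, or for sites with more than two alleles.
#' Mismatches fall into three categories: heterozygous by sequence but
#' homozygous on the array, homozygous by sequence but heterozygous on
#' the array, and opposite homozygotes.
#'
#' @param comparisons data.frame with columns marker, sample, ref_reads,
#'   alt_reads, array_call (AA/AB/BB/NoCall/OO...), n_alleles (optional,
#'   default 2).
#' @param config a [binomialTestConfig()].
#' @return list(table = per-comparison categories, summary = category
#'   counts and match percentage).
#' @export
compareSeqArray <- function(comparisons, config = binomialTestConfig()) {
  d <- comparisons
  if (is.null(d$n_alleles)) d$n_alleles <- 2L
  seq_gt <- binomialGenotype(d$ref_reads, d$alt_reads, config)
  category <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (d$array_call[i] %in% c("NoCall", "OO", "AO", "BO")) {
      category[i] <- "not_comparable(array_call)"
    } else if (d$n_alleles[i] > 2L) {
      category[i] <- "not_comparable(multiallelic)"
    } else if (seq_gt$genotype[i] == "no_call") {
      category[i] <- "not_comparable(min_reads)"
    } else {
      arr_het <- d$array_call[i] == "AB"
      seq_het <- seq_gt$genotype[i] == "het"
      if (seq_het && arr_het) category[i] <- "match"
      else if (seq_het && !arr_het) category[i] <- "het_seq_hom_array"
      else if (!seq_het && arr_het) category[i] <- "hom_seq_het_array"
      else {
        # both homozygous: compare which allele
        arr_allele <- if (d$array_call[i] == "AA") "ref" else "alt"
        category[i] <- if (arr_allele == seq_gt$major[i]) "match"
        else "opposite_homozygotes"
      }
    }
  }
  tab <- cbind(d, seq_genotype = seq_gt$genotype, category = category,
               stringsAsFactors = FALSE)
  comparable <- !startsWith(category, "not_comparable")
  summary <- as.list(table(category))
  summary$n_attempted <- nrow(d)
  summary$n_comparable <- sum(comparable)
  summary$match_pct <- if (any(comparable))
    100 * sum(category == "match") / sum(comparable) else NA_real_
  list(table = tab, summary = summary)
}

#' Minor allele frequency and polymorphism class
#'
#' Allele counts are collapsed from dosage genotypes (AA contributes two
#' A alleles, AB one of each, and so on); null alleles (O) count as an
#' allele class when present; NoCall entries are skipped. MAF is the
#' frequency of the least frequent allele present, 0 indicating
#' monomorphism. Classes: monomorphic (0), low (< 0.10), polymorphic
#' (>= 0.10), highly_polymorphic (>= 0.35).
#'
#' @param genotypes character vector of two-allele genotype strings.
#' @return list(maf, counts, class).
#' @examples
#' mafStats(rep(c("AA", "AB", "BB"), c(30, 20, 15)))  # 50/130 ~ 0.385
#' @export
mafStats <- function(genotypes) {
  g <- genotypes[genotypes != "NoCall"]
  alleles <- unlist(strsplit(g, ""))
  counts <- table(alleles)
  maf <- if (length(counts) < 2L) 0 else min(counts) / sum(counts)
  class <- if (maf == 0) "monomorphic"
  else if (maf < 0.10) "low"
  else if (maf < 0.35) "polymorphic"
  else "highly_polymorphic"
  list(maf = as.numeric(maf), counts = counts, class = class)
}

#' Largest marker gap on a chromosome
#'
#' Maximum distance between adjacent polymorphic marker positions;
#' optionally the chromosome ends (0 and `chrom_length`) count as
#' boundaries. An empty position set returns the chromosome length,
#' flagged.
#'
#' @param positions marker coordinates on one chromosome.
#' @param chrom_length chromosome length (required when
#'   `include_ends = TRUE`).
#' @param include_ends count the chromosome ends as gap boundaries.
#' @return list(gap, empty).
#' @examples
#' largestGap(c(100, 500, 4000))  # 3500
#' @export
largestGap <- function(positions, chrom_length = NULL, include_ends = FALSE) {
  if (!length(positions)) {
    if (is.null(chrom_length))
      stop("empty position set needs chrom_length")
    return(list(gap = chrom_length, empty = TRUE))
  }
  p <- sort(positions)
  if (include_ends) {
    if (is.null(chrom_length)) stop("include_ends = TRUE needs chrom_length")
    p <- c(0, p, chrom_length)
  }
  list(gap = if (length(p) > 1) max(diff(p)) else 0, empty = FALSE)
}
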