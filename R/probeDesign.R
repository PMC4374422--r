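#' Flank-polymorphism screen for a candidate probe site
#'
#' Classifies probe design from the polymorphism content of the tiled
#' flank: "not_recommended" when one or more polymorphisms lie within 20
#' bases of the site, or more than 2 within 24 bases; "neutral" when one
#' or two polymorphisms lie between 20 and 24 bases (i.e. at distances
#' 21-24) and none closer; "recommended" when no polymorphism lies within
#' 24 bases.
#'
#' @param table a [PanelVariantTable-class].
#' @param chrom,pos candidate coordinate.
#' @param strand "forward" counts the upstream flank (the probe body for a
#'   forward-strand probe ending at the site), "reverse" the downstream
#'   flank.
#' @param exception_pos coordinate exempted from counting (a haploSNP's
#'   destabiliser).
#' @return "recommended", "neutral" or "not_recommended".
#' @export
screenFlanks <- function(table, chrom, pos, strand = c("forward", "reverse"),
                         exception_pos = NULL) {
  strand <- match.arg(strand)
  pidx <- .positionIndex(table)
  sp <- pidx[[chrom]]
  excl <- c(pos, exception_pos)
  if (strand == "forward") {
    n20 <- .countInWindow(sp, pos - 20L, pos - 1L, exclude = excl)
    n24 <- .countInWindow(sp, pos - 24L, pos - 1L, exclude = excl)
  } else {
    n20 <- .countInWindow(sp, pos + 1L, pos + 20L, exclude = excl)
    n24 <- .countInWindow(sp, pos + 1L, pos + 24L, exclude = excl)
  }
  if (n20 >= 1L || n24 > 2L) "not_recommended"
  else if (n24 >= 1L) "neutral"
  else "recommended"
}

#' 16-mer genome-similarity screen
#'
#' Counts occurrences in the reference (both strands) of every 16-mer
#' substring of the probe, summed over the probe's `L - 15` 16-mers;
#' a probe fails ("not recommended") when the total exceeds
#' `max_matches` (default 300).
#'
#' @param probe probe sequence (length >= 16).
#' @param reference a [Biostrings::DNAStringSet].
#' @param max_matches failure threshold.
#' @return list(matches, pass).
#' @export
kmerUniqueness <- function(probe, reference, max_matches = 300L) {
  L <- nchar(probe)
  if (L < 16L) stop("probe must be at least 16 bases long")
  kmers <- vapply(seq_len(L - 15L), function(i) substr(probe, i, i + 15L), "")
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  fwd <- sum(Biostrings::vcountPDict(pd, reference))
  rev <- sum(Biostrings::vcountPDict(pd,
                                     Biostrings::reverseComplement(reference)))
  total <- fwd + rev
  list(matches = total, pass = total <= max_matches)
}

#' Classify an external reproducibility score
#'
#' The in-silico probe-quality score (a random-forest prediction trained
#' on human array data) is a pluggable input here, not re-trained:
#' below 0.4 is "not_recommended", 0.4-0.7 "neutral", above 0.7
#' "recommended"; a missing score is "unscored".
#'
#' @param score numeric in 0-1, or NA.
#' @return classification string (vectorised).
#' @export
classifyScore <- function(score) {
  out <- ifelse(is.na(score), "unscored",
                ifelse(score < 0.4, "not_recommended",
                       ifelse(score > 0.7, "recommended", "neutral")))
  out
}

.PLOIDY_REDUCING <- c("msnp", "haplosnp_snpsnp", "haplosnp_indelsnp",
                      "snp_in_insertion")
.STANDARD <- c("diallelic_snp", "indel", "diploid_parent_snp", "codon_based")

#' Array-inclusion eligibility of a screened candidate
#'
#' Standard categories (di-allelic SNPs, indels, diploid-derived and
#' codon-based SNPs) are admitted only when every screen is recommended;
#' ploidy-reducing categories (mSNPs and haploSNPs) are admitted when
#' screens are recommended or neutral, to fully populate the array. An
#' unscored external score is treated as neutral. Candidates failing the
#' 16-mer screen are always rejected. The returned priority follows the
#' array inclusion order: ploidy-reducing markers first, then remaining
#' octoploid categories, then diploid-derived, then codon-based.
#'
#' @param category candidate category string.
#' @param flank_class result of [screenFlanks()].
#' @param kmer_pass logical from [kmerUniqueness()].
#' @param score_class result of [classifyScore()].
#' @return list(admit, priority, reason).
#' @export
eligibility <- function(category, flank_class, kmer_pass = TRUE,
                        score_class = "unscored") {
  eff_score <- ifelse(score_class == "unscored", "neutral", score_class)
  classes <- c(flank_class, eff_score)
  priority <- if (category %in% .PLOIDY_REDUCING) 1L
  else if (category %in% c("diallelic_snp", "indel")) 2L
  else if (category == "diploid_parent_snp") 3L
  else 4L
  if (!kmer_pass)
    return(list(admit = FALSE, priority = priority, reason = "kmer_screen"))
  if (any(classes == "not_recommended"))
    return(list(admit = FALSE, priority = priority, reason = "not_recommended"))
  if (category %in% .STANDARD && any(classes != "recommended"))
    return(list(admit = FALSE, priority = priority,
                reason = "neutral_not_allowed_for_standard_category"))
  list(admit = TRUE, priority = priority, reason = "")
}

# apply a destabiliser edit to the reference, then return `len` bases
# ending immediately before `pos` (forward) or starting immediately after
# (reverse, reverse-complemented): haploSNP probes anchor across the
# critical destabilising form
.editedFlank <- function(reference, chrom, pos, len, side,
                         destab_pos = NA, destab_type = NA,
                         destab_alt = NA) {
  pad <- len + 12L
  L <- Biostrings::width(reference[chrom])
  if (side == "up") {
    lo <- max(1L, pos - pad); hi <- pos - 1L
  } else {
    lo <- pos + 1L; hi <- min(L, pos + pad)
  }
  s <- strsplit(as.character(Biostrings::subseq(reference[[chrom]], lo, hi)),
                "")[[1]]
  if (!is.na(destab_pos) && destab_pos >= lo && destab_pos <= hi) {
    i <- destab_pos - lo + 1L
    if (destab_type == "snp") {
      s[i] <- destab_alt
    } else if (destab_type == "ins") {
      s <- append(s, strsplit(substring(destab_alt, 2L), "")[[1]], after = i)
    } else if (destab_type == "del") {
      dl <- nchar(destab_alt)  # alt is the anchor; ref length implies span
      # destab_alt holds the alt (anchor); deletion span follows the anchor
      # and is encoded by the destabiliser's ref allele length upstream;
      # span length is carried in attr if provided
      span <- attr(destab_alt, "span") %||% 0L
      if (span > 0L && i + span <= length(s)) s <- s[-((i + 1L):(i + span))]
    }
  }
  if (side == "up") {
    out <- tail(s, len)
    paste(out, collapse = "")
  } else {
    out <- head(s, len)
    paste(rev(chartr("ACGT", "TGCA", out)), collapse = "")
  }
}

#' Build the probe tiling for one candidate
#'
#' Probe geometry (a package design choice; the safety windows guarantee
#' the sequence content): a non-allele-specific probe is `probe_length`
#' bases of the tiled strand ending immediately 5' of the interrogated
#' position; allele-specific probes carry the interrogated base at their
#' 3' terminus (length `probe_length + 1`). Per tiled strand, standard
#' non-A/T-G/C markers get one probe; A/T or C/G markers (permitted in the
#' indel and haploSNP categories) get two allele-specific probes; mSNPs
#' get four allele-specific probes, one per base. SNP-SNP and indel-SNP
#' haploSNPs can be tiled only on the strand whose probe extends across
#' the destabilising site; probes for those categories are built on the
#' destabilised (critical-form) template.
#'
#' @param candidate one row of a candidate data.frame.
#' @param strands character vector of strands to tile ("forward",
#'   "reverse").
#' @param reference a [Biostrings::DNAStringSet].
#' @param probe_length probe body length in bases.
#' @return data.frame of probe specs: candidate id, strand, sequence,
#'   allele_specific, allele, probeset id.
#' @export
buildTiling <- function(candidate, strands = c("forward", "reverse"),
                        reference, probe_length = 30L) {
  stopifnot(nrow(candidate) == 1L)
  cat_ <- candidate$category
  single_strand <- cat_ %in% c("haplosnp_snpsnp", "haplosnp_indelsnp")
  if (single_strand) {
    bad <- setdiff(strands, candidate$strand)
    if (length(bad))
      stop(cat_, " sites can be probed only on the ", candidate$strand,
           " strand (requested: ", paste(bad, collapse = ", "), ")")
  }
  id <- sprintf("%s:%s:%d", cat_, candidate$chrom, candidate$pos)
  alleles <- strsplit(candidate$alleles, "/", fixed = TRUE)[[1]]
  out <- list()
  for (st in strands) {
    destab <- if (!is.na(candidate$destab_pos) &&
                  cat_ != "snp_in_insertion") candidate$destab_pos else NA
    flank <- .editedFlank(reference, candidate$chrom, candidate$pos,
                          probe_length, if (st == "forward") "up" else "down",
                          destab_pos = destab,
                          destab_type = candidate$destab_type,
                          destab_alt = candidate$destab_alt)
    interrogated <- if (cat_ == "msnp") BASES
    else if (isTRUE(candidate$atgc)) {
      a <- alleles[nchar(alleles) == 1L]
      if (length(a) < 2L) a <- unique(unlist(strsplit(alleles, "")))[1:2]
      a
    } else NA_character_
    if (length(interrogated) == 1L && is.na(interrogated)) {
      out[[length(out) + 1L]] <- data.frame(
        candidate = id, strand = st, sequence = flank,
        allele_specific = FALSE, allele = NA_character_,
        probeset = paste(id, st, sep = "|"), stringsAsFactors = FALSE)
    } else {
      base_on_strand <- if (st == "forward") interrogated
      else chartr("ACGT", "TGCA", interrogated)
      out[[length(out) + 1L]] <- data.frame(
        candidate = id, strand = st,
        sequence = paste0(flank, base_on_strand),
        allele_specific = TRUE, allele = interrogated,
        probeset = paste(id, st, sep = "|"), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Construct a site-level tiling plan
#'
#' A tiling plan is the site-by-site accounting input of
#' [accountDesign()]: one row per target site recording its category, the
#' number of tiled strands, and whether the interrogated polymorphism is
#' an A/T or C/G pair (requiring an allele-specific probe pair per
#' strand).
#'
#' @param category marker category.
#' @param n_single,n_both counts of non-A/T-G/C sites tiled on one or
#'   both strands.
#' @param n_atgc_single,n_atgc_both counts of A/T-or-C/G sites tiled on
#'   one or both strands.
#' @return data.frame(category, strands, atgc).
#' @export
tilingPlan <- function(category, n_single = 0L, n_both = 0L,
                       n_atgc_single = 0L, n_atgc_both = 0L) {
  data.frame(
    category = category,
    strands = rep(c(1L, 2L, 1L, 2L),
                  c(n_single, n_both, n_atgc_single, n_atgc_both)),
    atgc = rep(c(FALSE, FALSE, TRUE, TRUE),
               c(n_single, n_both, n_atgc_single, n_atgc_both)),
    stringsAsFactors = FALSE)
}

# default per-category probeset convention for A/T-G/C allele-specific
# probe pairs: TRUE = the pair's intensities are combined into ONE
# probeset; FALSE = each allele-specific probe is its own probeset
.pairOneProbesetDefault <- function(category) {
  !(category %in% c("haplosnp_indelsnp", "snp_in_insertion"))
}

#' Probe / probeset / feature accounting for a tiling plan
#'
#' Per site and tiled strand: standard non-A/T-G/C markers use 1 probe and
#' 1 probeset; A/T-or-C/G markers use 2 allele-specific probes forming one
#' probeset (or two, depending on the category's convention); mSNPs use 4
#' probes (all four bases designed at the position) forming 6 probesets
#' (one per unordered base pair, C(4,2)). Features count every probe twice
#' (two replicates per probe on the array).
#'
#' @param plan a [tilingPlan()] data.frame (rows from several categories
#'   may be concatenated).
#' @param pair_one_probeset optional named logical vector overriding the
#'   per-category A/T-G/C probeset convention.
#' @return DesignSummary data.frame: one row per category plus a "total"
#'   row, with n_target_sites, n_single, n_both, n_probes, n_probesets,
#'   n_features.
#' @export
accountDesign <- function(plan, pair_one_probeset = NULL) {
  stopifnot(all(c("category", "strands", "atgc") %in% names(plan)))
  rows <- lapply(split(plan, plan$category), function(p) {
    cat_ <- p$category[1]
    pair1 <- if (!is.null(pair_one_probeset) && cat_ %in% names(pair_one_probeset))
      pair_one_probeset[[cat_]] else .pairOneProbesetDefault(cat_)
    probes_ps <- ifelse(p$category == "msnp", 4L, ifelse(p$atgc, 2L, 1L))
    psets_ps <- ifelse(p$category == "msnp", 6L,
                       ifelse(p$atgc, if (pair1) 1L else 2L, 1L))
    data.frame(category = cat_,
               n_target_sites = nrow(p),
               n_single = sum(p$strands == 1L),
               n_both = sum(p$strands == 2L),
               n_probes = sum(probes_ps * p$strands),
               n_probesets = sum(psets_ps * p$strands),
               n_features = 2L * sum(probes_ps * p$strands),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(category = "total",
                      n_target_sites = sum(out$n_target_sites),
                      n_single = sum(out$n_single),
                      n_both = sum(out$n_both),
                      n_probes = sum(out$n_probes),
                      n_probesets = sum(out$n_probesets),
                      n_features = sum(out$n_features),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
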