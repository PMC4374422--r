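#' Discovery-pipeline configuration
#'
#' Houses every numeric threshold of the candidate-discovery pipelines.
#' Defaults are the array-design values: SNP variants need at least 3
#' supporting reads summed across all panel files and indels at least 2;
#' marker variants must be present in >= 2 and absent in >= 2 members of
#' the filtration subpanel; SNP flank windows are 24/24 bp and indel
#' windows 24/30 bp (the extra 6 bp covering the candidate indel's own
#' 3-6 bp length); destabilising HSVs must lie within 6 bp (SNP-SNP) or
#' 14 bp (indel-SNP, 4-6 bp indels) of the marker, and SNP-in-insertion
#' markers sit inside a 3-6 bp insertion; a 24 bp window around the marker
#' must be free of any variant other than the destabiliser.
#'
#' @param min_reads_snp,min_reads_indel read-count thresholds (summed
#'   across all panel files).
#' @param min_present,min_absent presence/absence thresholds on the
#'   filtration subpanel.
#' @param subpanel one of "GDP", "HD16", "HD20".
#' @param snp_up,snp_down,indel_up,indel_down flank windows in bp.
#' @param snpsnp_max_offset,indelsnp_max_offset haploSNP pairing distances.
#' @param indelsnp_size_range,insertion_size_range destabiliser indel and
#'   insertion lengths (bp).
#' @param indel_size_range candidate marker indel lengths (bp).
#' @param clean_window haploSNP clean-window length (bp).
#' @param genic_mode "CDS", "genic" or "none".
#' @param exclude_unanchored drop candidates on unanchored contigs.
#' @param unanchored_chroms contig names treated as unanchored.
#' @return classed list "pipelineConfig".
#' @export
pipelineConfig <- function(min_reads_snp = 3L, min_reads_indel = 2L,
                           min_present = 2L, min_absent = 2L,
                           subpanel = c("GDP", "HD16", "HD20"),
                           snp_up = 24L, snp_down = 24L,
                           indel_up = 24L, indel_down = 30L,
                           snpsnp_max_offset = 6L, indelsnp_max_offset = 14L,
                           indelsnp_size_range = c(4L, 6L),
                           insertion_size_range = c(3L, 6L),
                           indel_size_range = c(3L, 6L),
                           clean_window = 24L,
                           genic_mode = c("none", "CDS", "genic"),
                           exclude_unanchored = FALSE,
                           unanchored_chroms = character()) {
  subpanel <- match.arg(subpanel)
  genic_mode <- match.arg(genic_mode)
  stopifnot(snp_up > 0, snp_down > 0, indel_up > 0, indel_down > 0,
            clean_window > 0,
            indelsnp_size_range[1] <= indelsnp_size_range[2],
            insertion_size_range[1] <= insertion_size_range[2],
            indel_size_range[1] <= indel_size_range[2])
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Minimum variant read-count filter
#'
#' Keeps a variant iff its supporting reads, summed across all panel
#' files, reach the type-specific threshold (default 3 for SNPs, 2 for
#' indels); intended to remove variants due to sequencing error.
#'
#' @param table a [PanelVariantTable-class].
#' @param idx variant row indices (default all).
#' @param config a [pipelineConfig()].
#' @return logical vector along `idx`.
#' @export
readCountFilter <- function(table, idx = seq_len(nrow(table@variants)),
                            config = pipelineConfig()) {
  total <- rowSums(table@support[idx, , drop = FALSE])
  thr <- ifelse(table@variants$type[idx] == "snp",
                config$min_reads_snp, config$min_reads_indel)
  total >= thr
}

#' Minimum presence / minimum absence filter
#'
#' A marker variant must be present (>= 1 supporting read) in at least
#' `min_present` and absent in at least `min_absent` members of the
#' filtration subpanel: together these ensure the variant segregates in
#' the panel and is a marker rather than a fixed homoeologous sequence
#' variant.
#'
#' @inheritParams readCountFilter
#' @param check_absence_only when TRUE only the absence condition is
#'   enforced (the indel pipeline's convention).
#' @return data.frame(keep, reason) along `idx`; reasons are "" for kept
#'   variants, "HSV-like" for variants present in every subpanel member,
#'   "insufficient presence" or "insufficient absence" otherwise.
#' @export
presenceAbsenceFilter <- function(table, idx = seq_len(nrow(table@variants)),
                                  config = pipelineConfig(),
                                  check_absence_only = FALSE) {
  files <- subpanel(table, config$subpanel)
  if (length(files) < config$min_present + config$min_absent)
    stop("subpanel ", config$subpanel, " has ", length(files),
         " files; cannot require presence >= ", config$min_present,
         " and absence >= ", config$min_absent)
  pres <- rowSums(table@support[idx, files, drop = FALSE] > 0L)
  abs_n <- length(files) - pres
  keep_p <- pres >= config$min_present | check_absence_only
  keep_a <- abs_n >= config$min_absent
  reason <- rep("", length(idx))
  reason[!keep_a & pres == length(files)] <- "HSV-like"
  reason[!keep_a & pres < length(files)] <- "insufficient absence"
  reason[keep_a & !keep_p] <- "insufficient presence"
  data.frame(keep = keep_p & keep_a, reason = reason,
             stringsAsFactors = FALSE)
}

#' A/T-G/C allele-pair filter
#'
#' Drops SNPs whose unordered allele pair is {A,T} or {G,C}: those require
#' two allele-specific probes on the array, whereas A/C, A/G, C/T and G/T
#' polymorphisms are interrogated with a single probe.
#'
#' @param ref_allele,alt_allele single-base alleles.
#' @return logical: TRUE = keep.
#' @export
atGcFilter <- function(ref_allele, alt_allele) {
  if (any(nchar(ref_allele) != 1L) || any(nchar(alt_allele) != 1L) ||
      !all(c(ref_allele, alt_allele) %in% BASES))
    stop("atGcFilter applies to single-base SNP alleles only")
  !.isAtGcPair(ref_allele, alt_allele)
}

#' Genic / CDS location filter
#'
#' In "CDS" mode keeps only coordinates overlapping coding sequence; in
#' "genic" mode coordinates within gene extents (CDS plus introns); "none"
#' keeps everything. Candidates on unanchored contigs are dropped when the
#' config requests it (they cannot be subjected to CDS confirmation).
#'
#' @param chrom,pos coordinate vectors.
#' @param gene_models [GenomicRanges::GRanges] with a `type` column.
#' @param config a [pipelineConfig()].
#' @return logical keep vector.
#' @export
genicFilter <- function(chrom, pos, gene_models = NULL,
                        config = pipelineConfig()) {
  keep <- rep(TRUE, length(pos))
  if (config$exclude_unanchored)
    keep <- keep & !(chrom %in% config$unanchored_chroms)
  if (config$genic_mode == "none" || is.null(gene_models))
    return(keep)
  sel <- if (config$genic_mode == "CDS") gene_models$type == "CDS"
         else gene_models$type == "gene"
  target <- gene_models[sel]
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::countOverlaps(q, target, ignore.strand = TRUE) > 0
  keep & hits
}

# sorted unique variant positions per chromosome, for fast window scans
.positionIndex <- function(table, extra = NULL) {
  pos_df <- table@variants[, c("chrom", "pos")]
  if (!is.null(extra)) pos_df <- rbind(pos_df, extra[, c("chrom", "pos")])
  lapply(split(pos_df$pos, pos_df$chrom), function(p) sort(unique(p)))
}

.countInWindow <- function(sorted_pos, lo, hi, exclude = integer()) {
  if (is.null(sorted_pos) || hi < lo) return(0L)
  exclude <- unique(exclude)
  n <- findInterval(hi, sorted_pos) - findInterval(lo - 1L, sorted_pos)
  n - sum(exclude >= lo & exclude <= hi & exclude %in% sorted_pos)
}

#' Flank-safety status of a candidate site
#'
#' A window is safe iff no panel variant other than the candidate itself
#' (and at most one allowed exception, the haploSNP destabilisation site)
#' falls within it. Returns "BothSafe", "UpSafe-only", "DownSafe-only" or
#' "Unsafe".
#'
#' @param table a [PanelVariantTable-class].
#' @param chrom,pos candidate coordinate.
#' @param up_window,down_window window lengths in bp.
#' @param exception_pos optional coordinate exempted from the scan.
#' @param pos_index optional precomputed [.positionIndex]-style list (used
#'   internally to avoid recomputation); when supplied it may include
#'   extra positions (e.g. a diploid sample's variants).
#' @return status string.
#' @export
flankSafety <- function(table, chrom, pos, up_window = 24L,
                        down_window = 24L, exception_pos = NULL,
                        pos_index = NULL) {
  if (is.null(pos_index)) pos_index <- .positionIndex(table)
  sp <- pos_index[[chrom]]
  excl <- c(pos, exception_pos)
  up_n <- .countInWindow(sp, pos - up_window, pos - 1L, exclude = excl)
  down_n <- .countInWindow(sp, pos + 1L, pos + down_window, exclude = excl)
  if (up_n == 0L && down_n == 0L) "BothSafe"
  else if (up_n == 0L) "UpSafe-only"
  else if (down_n == 0L) "DownSafe-only"
  else "Unsafe"
}
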