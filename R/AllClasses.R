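#' @import methods
#' @importFrom stats rpois rbinom rnorm runif median quantile var dnorm pbinom setNames
#' @importFrom utils head tail write.table read.delim
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Intensity model for simulated genotype clusters
#'
#' Deterministic two-channel cluster-centre model: the A-channel signal of a
#' sample is `nA * intensityA + background` and the B channel is
#' `nB * intensityB + background`, where `nA`/`nB` count the A and B alleles
#' over all homoeologous copies that hybridise to the probe. All three
#' constants default to 100 intensity units, which places a diploid
#' heterozygote at (200, 200) and an octoploid B-fixed heterozygote
#' (ABBBBBBB) at (200, 800).
#'
#' @slot intensityA per-A-allele signal increment (arbitrary units, > 0)
#' @slot intensityB per-B-allele signal increment (> 0)
#' @slot background background signal added to both channels (> 0)
#' @export
setClass("ClusterCenterModel",
  representation(intensityA = "numeric", intensityB = "numeric",
                 background = "numeric"),
  prototype(intensityA = 100, intensityB = 100, background = 100),
  validity = function(object) {
    if (any(c(object@intensityA, object@intensityB, object@background) <= 0))
      return("all intensity model constants must be > 0 (zero background is rejected)")
    TRUE
  })

#' @param intensityA,intensityB,background model constants, see slots.
#' @rdname ClusterCenterModel-class
#' @export
clusterCenterModel <- function(intensityA = 100, intensityB = 100,
                               background = 100) {
  new("ClusterCenterModel", intensityA = intensityA, intensityB = intensityB,
      background = background)
}

#' Configuration of the synthetic allo-octoploid panel generator
#'
#' Fully determines a synthetic discovery panel: a random diploid reference,
#' `n_subgenomes` diverged homoeologous subgenomes collapsed onto its
#' coordinate system, fixed homoeologous sequence variants (HSVs),
#' segregating marker variants of every array category, deletion blocks of
#' locally reduced ploidy, per-accession read-depth observations and a
#' diploid outgroup sample. All rates are events per kilobase of reference.
#' The same seed reproduces every output byte for byte.
#'
#' @slot seed integer; drives all randomness.
#' @slot ref_length total reference length in bp.
#' @slot n_chromosomes number of chromosomes the reference is split into.
#' @slot n_subgenomes number of homoeologous subgenomes (>= 2; 4 emulates an
#'   AABBCCDD allo-octoploid).
#' @slot n_accessions number of panel accessions.
#' @slot duplicate_first_accession logical; when TRUE the first accession
#'   contributes two VCF files (as a twice-sequenced accession would),
#'   giving `n_accessions + 1` files.
#' @slot hsv_rate fixed HSVs per kb (inter-subgenome divergence; a free
#'   parameter of the simulation, not an empirical value).
#' @slot marker_rate segregating di-allelic marker SNPs per kb.
#' @slot indel_marker_rate segregating 3-6 bp marker indels per kb.
#' @slot msnp_rate multi-allelic marker sites per kb.
#' @slot haplosnp_rate haploSNP marker/destabiliser pairs per kb (split
#'   across the three strategies).
#' @slot diploid_marker_rate heterozygous sites per kb in the diploid
#'   outgroup sample.
#' @slot decoy_rate per kb of planted filter-violating decoys.
#' @slot deletion_block_count,deletion_block_length number and length (bp) of
#'   fixed subgenome-deletion blocks (biological ploidy reduction).
#' @slot mean_depth per-file mean fold coverage (length `n_files`).
#' @slot min_alt_reads minimum supporting reads for a variant record to be
#'   emitted in a carrier's VCF (emulates the caller's minimum
#'   alternate-observation count).
#' @slot gene_fraction fraction of the reference covered by two-exon genes.
#' @slot intensity_model a [ClusterCenterModel-class].
#' @slot noise_sd standard deviation of multiplicative log-normal intensity
#'   noise (0 = noise-free centres).
#' @export
setClass("SimConfig",
  representation(seed = "integer", ref_length = "integer",
    n_chromosomes = "integer", n_subgenomes = "integer",
    n_accessions = "integer", duplicate_first_accession = "logical",
    hsv_rate = "numeric", marker_rate = "numeric",
    indel_marker_rate = "numeric", msnp_rate = "numeric",
    haplosnp_rate = "numeric", diploid_marker_rate = "numeric",
    decoy_rate = "numeric", deletion_block_count = "integer",
    deletion_block_length = "integer", mean_depth = "numeric",
    min_alt_reads = "integer", gene_fraction = "numeric",
    intensity_model = "ClusterCenterModel", noise_sd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n_subgenomes < 2L) msg <- c(msg, "n_subgenomes must be >= 2")
    rates <- c(object@hsv_rate, object@marker_rate, object@indel_marker_rate,
               object@msnp_rate, object@haplosnp_rate,
               object@diploid_marker_rate, object@decoy_rate)
    if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
    if (object@ref_length < 1000L) msg <- c(msg, "ref_length must be >= 1000 bp")
    if (object@n_accessions < 4L)
      msg <- c(msg, "need at least 4 accessions for presence/absence filters")
    n_files <- object@n_accessions + as.integer(object@duplicate_first_accession)
    if (length(object@mean_depth) != n_files)
      msg <- c(msg, sprintf("mean_depth must have one value per file (%d)", n_files))
    if (object@gene_fraction < 0 || object@gene_fraction > 0.9)
      msg <- c(msg, "gene_fraction must be in [0, 0.9]")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' Build a simulation configuration
#'
#' Defaults emulate the discovery-panel conditions of an octoploid array
#' project at desk scale: 19 accessions represented by 20 VCF files (one
#' accession sequenced twice), file coverages spanning 4-31x such that ten
#' files reach 16x (an "HD-16" subpanel, including both files of the
#' duplicated accession) and eight reach 20x ("HD-20", excluding the
#' lower-coverage duplicate).
#'
#' @param seed integer seed; fully determines all outputs.
#' @param ref_length,n_chromosomes,n_subgenomes,n_accessions see slots.
#' @param duplicate_first_accession see slots.
#' @param hsv_rate,marker_rate,indel_marker_rate,msnp_rate,haplosnp_rate
#'   planting rates per kb.
#' @param diploid_marker_rate,decoy_rate planting rates per kb.
#' @param deletion_block_count,deletion_block_length deletion-block geometry.
#' @param mean_depth per-file coverages; NULL uses the default ladder above.
#' @param min_alt_reads caller minimum alternate-observation count.
#' @param gene_fraction fraction of reference covered by gene models.
#' @param intensity_model a [ClusterCenterModel-class].
#' @param noise_sd multiplicative intensity noise SD.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, ref_length = 50000L)
#' @export
simConfig <- function(seed = 1L, ref_length = 500000L, n_chromosomes = 2L,
                      n_subgenomes = 4L, n_accessions = 19L,
                      duplicate_first_accession = TRUE,
                      hsv_rate = 2, marker_rate = 0.2,
                      indel_marker_rate = 0.06, msnp_rate = 0.06,
                      haplosnp_rate = 0.18, diploid_marker_rate = 0.06,
                      decoy_rate = 0.1,
                      deletion_block_count = 4L,
                      deletion_block_length = 10000L,
                      mean_depth = NULL, min_alt_reads = 2L,
                      gene_fraction = 0.6,
                      intensity_model = clusterCenterModel(),
                      noise_sd = 0.05) {
  n_files <- n_accessions + as.integer(duplicate_first_accession)
  if (is.null(mean_depth)) {
    # ladder: 8 files >= 20x (HD-20), plus the duplicate file at 17x and one
    # at 16x complete HD-16; the rest fall below 16x
    hi <- c(31, 28, 26, 24, 23, 22, 21, 20)
    mid <- c(17, 16)
    n_low <- n_files - length(hi) - length(mid)
    if (n_low < 0) stop("too few files for the default coverage ladder; supply mean_depth")
    low <- if (n_low) seq(14, 4, length.out = n_low) else numeric()
    # file 1 = accession 1 (high coverage), file 2 = its duplicate at 17x
    mean_depth <- c(hi[1], mid[1], hi[-1], mid[-1], low)
  }
  new("SimConfig", seed = as.integer(seed), ref_length = as.integer(ref_length),
      n_chromosomes = as.integer(n_chromosomes),
      n_subgenomes = as.integer(n_subgenomes),
      n_accessions = as.integer(n_accessions),
      duplicate_first_accession = duplicate_first_accession,
      hsv_rate = hsv_rate, marker_rate = marker_rate,
      indel_marker_rate = indel_marker_rate, msnp_rate = msnp_rate,
      haplosnp_rate = haplosnp_rate, diploid_marker_rate = diploid_marker_rate,
      decoy_rate = decoy_rate,
      deletion_block_count = as.integer(deletion_block_count),
      deletion_block_length = as.integer(deletion_block_length),
      mean_depth = mean_depth, min_alt_reads = as.integer(min_alt_reads),
      gene_fraction = gene_fraction, intensity_model = intensity_model,
      noise_sd = noise_sd)
}

#' Synthetic discovery panel
#'
#' Container returned by [generatePanel()]: the reference, gene models,
#' per-file variant observations, the diploid outgroup VCF, the deletion
#' blocks and the ground-truth table of every planted variant.
#'
#' @slot reference a [Biostrings::DNAStringSet] of chromosomes.
#' @slot genes a [GenomicRanges::GRanges] with gene/exon/CDS features.
#' @slot vcfs named list (one per file) of variant-record data.frames with
#'   columns chrom, pos, ref, alt, type, DP, RO, AO.
#' @slot diploid_vcf variant records of the diploid outgroup sample.
#' @slot truth ground-truth data.frame (see [generatePanel()]).
#' @slot deletions data.frame of deletion blocks (chrom, start, end,
#'   n_subgenomes_deleted).
#' @slot file_coverages named numeric, mean coverage per file.
#' @slot file_accessions named character, file id -> accession id.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SyntheticPanel",
  representation(reference = "DNAStringSet", genes = "GRanges",
    vcfs = "list", diploid_vcf = "data.frame", truth = "data.frame",
    deletions = "data.frame", file_coverages = "numeric",
    file_accessions = "character", config = "SimConfig"))

setMethod("show", "SyntheticPanel", function(object) {
  cat("SyntheticPanel:", sum(Biostrings::width(object@reference)), "bp reference in",
      length(object@reference), "chromosome(s)\n")
  cat("  files:", length(object@vcfs), " accessions:",
      length(unique(object@file_accessions)), "\n")
  cat("  planted truth records:", nrow(object@truth), "(",
      paste(names(table(object@truth$kind)), table(object@truth$kind),
            collapse = ", "), ")\n")
  invisible(object)
})

#' Union table of panel variant observations
#'
#' One row of `variants` per distinct (coordinate, alternate allele) after
#' left-aligned minimal-representation normalisation; `support` and `depth`
#' hold per-file summed supporting reads and site depth. Presence of a
#' variant in a file means at least one supporting read in that file.
#'
#' @slot variants data.frame(chrom, pos, ref, alt, type) with
#'   type in snp/ins/del.
#' @slot support integer matrix, variants x files, supporting reads.
#' @slot depth integer matrix, variants x files, total site depth.
#' @slot files character vector of file ids (columns of the matrices).
#' @slot accessions named character, file id -> accession id.
#' @slot subpanels named list of file-id subsets (e.g. GDP, HD16, HD20).
#' @export
setClass("PanelVariantTable",
  representation(variants = "data.frame", support = "matrix",
    depth = "matrix", files = "character", accessions = "character",
    subpanels = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@variants) != nrow(object@support))
      msg <- c(msg, "support matrix must have one row per variant")
    if (!identical(dim(object@support), dim(object@depth)))
      msg <- c(msg, "support and depth dimensions differ")
    if (ncol(object@support) != length(object@files))
      msg <- c(msg, "one support column per file required")
    if (any(object@support > object@depth))
      msg <- c(msg, "supporting reads cannot exceed site depth")
    bad <- setdiff(unlist(object@subpanels), object@files)
    if (length(bad)) msg <- c(msg, "subpanel references unknown files")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

setMethod("show", "PanelVariantTable", function(object) {
  nsite <- nrow(unique(object@variants[, c("chrom", "pos")]))
  cat("PanelVariantTable:", nrow(object@variants), "distinct variants over",
      nsite, "sites;", length(object@files), "files,",
      length(unique(object@accessions)), "accessions\n")
  cat("  subpanels:", paste(names(object@subpanels), lengths(object@subpanels),
                            sep = "=", collapse = ", "), "\n")
  invisible(object)
})

#' @describeIn PanelVariantTable-class the variant data.frame.
#' @param x a `PanelVariantTable`.
#' @export
variantRecords <- function(x) x@variants

#' @describeIn PanelVariantTable-class per-file supporting-read matrix.
#' @export
supportMatrix <- function(x) x@support

#' @describeIn PanelVariantTable-class file ids.
#' @export
panelFiles <- function(x) x@files

#' @describeIn PanelVariantTable-class file ids of a named subpanel
#'   ("GDP", "HD16" or "HD20").
#' @param name subpanel name.
#' @export
subpanel <- function(x, name = "GDP") {
  if (!name %in% names(x@subpanels))
    stop("unknown subpanel: ", name)
  x@subpanels[[name]]
}
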