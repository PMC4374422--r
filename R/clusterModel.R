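#' Deterministic cluster centre for an allele configuration
#'
#' `A = nA * intensityA + background`, `B = nB * intensityB + background`.
#'
#' @param nA,nB allele counts over all hybridising homoeologous copies.
#' @param model a [ClusterCenterModel-class].
#' @return numeric c(A, B).
#' @examples
#' clusterCenter(1, 1)   # diploid AB: (200, 200)
#' clusterCenter(1, 7)   # octoploid ABBBBBBB: (200, 800)
#' @export
clusterCenter <- function(nA, nB, model = clusterCenterModel()) {
  validObject(model)
  stopifnot(nA >= 0, nB >= 0)
  c(A = nA * model@intensityA + model@background,
    B = nB * model@intensityB + model@background)
}

#' Contrast / size transform of two-channel intensities
#'
#' The standard log-ratio / mean-log form: `contrast = log2(A/B)` and
#' `size = (log2 A + log2 B) / 2`. A balanced diploid heterozygote
#' (200, 200) and the tetraploid AABB configuration (300, 300) both land
#' at contrast 0; B-fixed octoploid clusters have negative contrast.
#'
#' @param A,B positive channel intensities (vectorised).
#' @return data.frame(contrast, size).
#' @export
contrastSize <- function(A, B) {
  stopifnot(all(A > 0), all(B > 0))
  data.frame(contrast = log2(A / B), size = (log2(A) + log2(B)) / 2)
}

# quantile-initialised EM for a 1-D k-component Gaussian mixture;
# deterministic given the data
.em1d <- function(x, k, iter = 200L, tol = 1e-8, var_floor = 1e-6) {
  n <- length(x)
  mu <- as.numeric(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                            type = 1))
  sd2 <- rep(max(var(x) / k^2, var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * dnorm(x, mu[j], sqrt(sd2[j])), numeric(n))
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    post <- dens / rs
    ll <- sum(log(rs))
    nk <- colSums(post)
    w <- nk / n
    mu <- colSums(post * x) / nk
    sd2 <- pmax(colSums(post * (x - rep(mu, each = n))^2) / nk, var_floor)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sd2 = sd2, w = w, post = post, ll = ll, k = k)
}

.bic <- function(fit, n) -2 * fit$ll + (3 * fit$k - 1) * log(n)

#' Call genotypes from contrast/size values
#'
#' A simplified, documented genotype caller (a stand-in for proprietary
#' array-calling software, not a reimplementation of it): samples in a
#' low-size cluster (mean size more than `otv_size_delta` below the
#' overall median) are first set aside as potential null-allele (OTV)
#' samples; the remaining contrasts are fit with a 1-D Gaussian mixture of
#' up to `max_k` components (quantile-initialised EM, component count by
#' BIC unless `k` is given). Cluster labels are assigned by decreasing
#' contrast: AA / AB / BB for three clusters, AA / BB for two, and the
#' sign of the centre for one. The confidence of a call is one minus the
#' posterior probability of its component; calls with confidence above
#' `conf_threshold` become "NoCall". Exactly repeated contrast values
#' (noise-free data) are resolved without EM, reproducing the truth
#' exactly.
#'
#' @param contrast,size numeric vectors (size may be NULL to disable OTV
#'   detection).
#' @param k fixed component count, or NULL for BIC selection over
#'   1..`max_k`.
#' @param max_k maximum number of non-OTV components.
#' @param conf_threshold NoCall threshold on 1 - posterior (stringent
#'   default 0.01; the permissive setting is 0.15).
#' @param otv_size_delta size drop (log2 units) defining the low-size OTV
#'   cluster.
#' @return list(call, confidence, centers (named contrast values),
#'   otv (logical), k).
#' @export
callGenotypes <- function(contrast, size = NULL, k = NULL, max_k = 3L,
                          conf_threshold = 0.01, otv_size_delta = 1.0) {
  n <- length(contrast)
  stopifnot(n >= 1L)
  otv <- rep(FALSE, n)
  if (!is.null(size) && n >= 4L) {
    med <- median(size)
    low <- size < med - otv_size_delta
    # a low-size cluster must be a minority set clearly detached in size
    if (any(low) && mean(low) < 0.5) otv <- low
  }
  x <- contrast[!otv]
  call <- rep(NA_character_, n)
  confidence <- rep(0, n)
  ux <- sort(unique(round(x, 9)), decreasing = TRUE)
  if (length(ux) <= max_k && length(ux) >= 1L) {
    kk <- length(ux)
    labs <- .clusterLabels(ux, kk)
    idx <- match(round(x, 9), ux)
    call[!otv] <- labs[idx]
    centers <- setNames(ux, labs)
  } else {
    fits <- if (is.null(k))
      lapply(seq_len(min(max_k, length(ux))), function(kk) .em1d(x, kk))
    else list(.em1d(x, min(k, length(ux))))
    best <- fits[[which.min(vapply(fits, .bic, 0, n = length(x)))]]
    ord <- order(best$mu, decreasing = TRUE)
    labs <- .clusterLabels(best$mu[ord], best$k)
    comp <- max.col(best$post)
    conf <- 1 - best$post[cbind(seq_along(x), comp)]
    call[!otv] <- labs[match(comp, ord)]
    confidence[!otv] <- conf
    centers <- setNames(best$mu[ord], labs)
  }
  call[otv] <- "OTV"
  idx <- which(!otv)
  call[idx[confidence[idx] > conf_threshold]] <- "NoCall"
  list(call = call, confidence = confidence, centers = centers,
       otv = otv, k = length(centers))
}

.clusterLabels <- function(centers_desc, k) {
  if (k == 3L) c("AA", "AB", "BB")
  else if (k == 2L) c("AA", "BB")
  else if (abs(centers_desc[1]) < 1e-9) "AB"
  else if (centers_desc[1] > 0) "AA" else "BB"
}

#' Homozygous Ratio Offset (HomRO)
#'
#' Displacement from zero contrast of the homozygous cluster closest to
#' it, signed so that homozygous clusters flanking zero give positive
#' values and clusters offset to the same side give negative values:
#' `HomRO = min(contrast_AA, -contrast_BB)` over the homozygous clusters
#' present. Loci clustering like a diploid have HomRO at or above the
#' threshold (default 0.3); polyploid-like loci fall below it (negative
#' or near zero).
#'
#' @param centers named contrast centres; names among AA, AB, BB.
#' @param threshold diploid-likeness threshold.
#' @return list(value, ploidy_pattern) with pattern "diploid_like" or
#'   "polyploid_like".
#' @examples
#' cs <- contrastSize(c(300, 100), c(100, 300))
#' homro(setNames(cs$contrast, c("AA", "BB")))  # log2(3), diploid-like
#' @export
homro <- function(centers, threshold = 0.3) {
  vals <- c(if ("AA" %in% names(centers)) centers[["AA"]],
            if ("BB" %in% names(centers)) -centers[["BB"]])
  if (!length(vals))
    stop("HomRO requires at least one homozygous cluster")
  v <- min(vals)
  list(value = v,
       ploidy_pattern = if (v >= threshold) "diploid_like" else "polyploid_like")
}

#' Quality-class thresholds for the SNP classifier
#'
#' @param call_rate_min minimum genotype call rate (markers below are
#'   CallRate Below Threshold).
#' @param n_minor_hom minimum count of minor-homozygote samples.
#' @param var_mult cluster-variance multiplier: a cluster fails its
#'   variance filter when its variance exceeds `var_mult` times the
#'   supplied reference (median same-genotype) variance.
#' @param ref_var_y,ref_var_x reference variances for the size (Y) and
#'   contrast (X) dimensions; NA disables the corresponding filters.
#' @param homro_threshold HomRO diploid-likeness threshold.
#' @return classed list "qualityThresholds".
#' @export
qualityThresholds <- function(call_rate_min = 0.97, n_minor_hom = 3L,
                              var_mult = 4, ref_var_y = NA_real_,
                              ref_var_x = NA_real_,
                              homro_threshold = 0.3) {
  structure(list(call_rate_min = call_rate_min, n_minor_hom = n_minor_hom,
                 var_mult = var_mult, ref_var_y = ref_var_y,
                 ref_var_x = ref_var_x, homro_threshold = homro_threshold),
            class = "qualityThresholds")
}

#' Classify one marker into an array quality class
#'
#' Decision order: call rate below 97% -> CRBT; one genotype cluster ->
#' MHR (monomorphic); an additional low-intensity cluster -> OTV; two
#' clusters -> NMH (no minor homozygote); three clusters -> PHR, subject
#' to the post-filters: 100% reproducibility of technical replicate
#' pairs, minor-homozygote count of at least `n_minor_hom`, and the four
#' cluster-variance filters (AB/AA/BB variance in the size dimension,
#' AB variance in the contrast dimension). A three-cluster marker failing
#' a post-filter keeps class PHR but `filtered = FALSE`, with the failing
#' filters named. Anything else is "Other". The function is total: every
#' input lands in exactly one class.
#'
#' @param calls character calls (AA/AB/BB/OTV/NoCall).
#' @param contrast,size per-sample values aligned with `calls`.
#' @param replicate_pairs optional 2-column matrix/data.frame of sample
#'   indices forming technical replicate pairs.
#' @param thresholds a [qualityThresholds()].
#' @param centers optional named cluster centres for HomRO (estimated
#'   from called samples when absent).
#' @return list: class, filtered, failed_filters, call_rate, n_clusters,
#'   minor_hom, reproducible, cluster_var (per cluster, contrast and
#'   size), homro, ploidy_pattern.
#' @export
classifyQuality <- function(calls, contrast, size = NULL,
                            replicate_pairs = NULL,
                            thresholds = qualityThresholds(),
                            centers = NULL) {
  n <- length(calls)
  stopifnot(length(contrast) == n)
  if (!is.null(replicate_pairs)) {
    rp <- as.matrix(replicate_pairs)
    if (any(rp < 1 | rp > n))
      stop("replicate map references unknown samples")
  }
  called <- calls != "NoCall"
  call_rate <- mean(called)
  genos <- setdiff(unique(calls[called]), "NoCall")
  geno_main <- setdiff(genos, "OTV")
  has_otv <- "OTV" %in% genos
  n_clusters <- length(geno_main) + has_otv

  if (is.null(centers) && length(geno_main)) {
    centers <- vapply(geno_main, function(g)
      mean(contrast[calls == g]), numeric(1))
  }
  hr <- if (any(c("AA", "BB") %in% names(centers)))
    homro(centers, thresholds$homro_threshold)
  else list(value = NA_real_, ploidy_pattern = NA_character_)

  base <- list(call_rate = call_rate, n_clusters = n_clusters,
               homro = hr$value, ploidy_pattern = hr$ploidy_pattern)

  if (call_rate < thresholds$call_rate_min)
    return(c(list(class = "CRBT", filtered = FALSE,
                  failed_filters = character()), base))
  if (length(geno_main) <= 1L && !has_otv)
    return(c(list(class = "MHR", filtered = FALSE,
                  failed_filters = character()), base))
  if (has_otv)
    return(c(list(class = "OTV", filtered = FALSE,
                  failed_filters = character()), base))
  if (length(geno_main) == 2L)
    return(c(list(class = "NMH", filtered = FALSE,
                  failed_filters = character()), base))
  if (length(geno_main) != 3L)
    return(c(list(class = "Other", filtered = FALSE,
                  failed_filters = character()), base))

  failed <- character()
  hom_counts <- c(AA = sum(calls == "AA"), BB = sum(calls == "BB"))
  minor_hom <- min(hom_counts)
  if (minor_hom < thresholds$n_minor_hom) failed <- c(failed, "nMinorHom")
  reproducible <- TRUE
  if (!is.null(replicate_pairs) && nrow(rp)) {
    reproducible <- all(calls[rp[, 1]] == calls[rp[, 2]])
    if (!reproducible) failed <- c(failed, "reproducibility")
  }
  cluster_var <- lapply(c(AA = "AA", AB = "AB", BB = "BB"), function(g) {
    i <- calls == g
    c(contrast = if (sum(i) > 1) var(contrast[i]) else 0,
      size = if (!is.null(size) && sum(i) > 1) var(size[i]) else 0)
  })
  if (!is.na(thresholds$ref_var_y)) {
    lim <- thresholds$var_mult * thresholds$ref_var_y
    for (g in c("AB", "AA", "BB"))
      if (cluster_var[[g]][["size"]] > lim)
        failed <- c(failed, paste0(g, ".varY"))
  }
  if (!is.na(thresholds$ref_var_x)) {
    if (cluster_var[["AB"]][["contrast"]] >
          thresholds$var_mult * thresholds$ref_var_x)
      failed <- c(failed, "AB.varX")
  }
  c(list(class = "PHR", filtered = length(failed) == 0L,
         failed_filters = failed, minor_hom = minor_hom,
         reproducible = reproducible, cluster_var = cluster_var), base)
}

#' Classify every marker of a cluster dataset
#'
#' Calls genotypes per marker, derives panel-level reference variances
#' (the median per-genotype cluster variance across markers, times the
#' configured multiplier) and classifies each marker. Returns a quality
#' report with one row per marker.
#'
#' @param dataset long data.frame: marker, sample, A, B (and optionally
#'   contrast/size, recomputed when absent).
#' @param replicate_pairs optional 2-column data.frame of sample ids
#'   (applied within each marker).
#' @param thresholds a [qualityThresholds()]; NA reference variances are
#'   filled in from the panel medians.
#' @param conf_threshold NoCall confidence threshold for the caller.
#' @return data.frame: marker, class, filtered, failed_filters,
#'   call_rate, n_clusters, homro, ploidy_pattern.
#' @export
classifyPanel <- function(dataset, replicate_pairs = NULL,
                          thresholds = qualityThresholds(),
                          conf_threshold = 0.01) {
  if (!all(c("contrast", "size") %in% names(dataset))) {
    cs <- contrastSize(dataset$A, dataset$B)
    dataset$contrast <- cs$contrast
    dataset$size <- cs$size
  }
  markers <- split(dataset, dataset$marker)
  calls <- lapply(markers, function(d)
    callGenotypes(d$contrast, d$size, conf_threshold = conf_threshold))
  # panel-level reference variances from per-marker per-genotype variances
  all_var <- unlist(lapply(names(markers), function(m) {
    d <- markers[[m]]; cl <- calls[[m]]$call
    vapply(intersect(unique(cl), c("AA", "AB", "BB")), function(g)
      if (sum(cl == g) > 1) var(d$size[cl == g]) else NA_real_, numeric(1))
  }))
  if (is.na(thresholds$ref_var_y))
    thresholds$ref_var_y <- median(all_var, na.rm = TRUE)
  all_var_x <- unlist(lapply(names(markers), function(m) {
    d <- markers[[m]]; cl <- calls[[m]]$call
    if (sum(cl == "AB") > 1) var(d$contrast[cl == "AB"]) else NA_real_
  }))
  if (is.na(thresholds$ref_var_x))
    thresholds$ref_var_x <- median(all_var_x, na.rm = TRUE)
  rows <- lapply(names(markers), function(m) {
    d <- markers[[m]]; cl <- calls[[m]]
    rp <- NULL
    if (!is.null(replicate_pairs))
      rp <- cbind(match(replicate_pairs[[1]], d$sample),
                  match(replicate_pairs[[2]], d$sample))
    q <- classifyQuality(cl$call, d$contrast, d$size, rp, thresholds,
                         centers = cl$centers)
    data.frame(marker = m, class = q$class, filtered = q$filtered,
               failed_filters = paste(q$failed_filters, collapse = ";"),
               call_rate = q$call_rate, n_clusters = q$n_clusters,
               homro = q$homro, ploidy_pattern = q$ploidy_pattern,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recode a marker's calls with null alleles (OTV recall)
#'
#' Samples in the low-intensity (OTV) cluster are homozygous for a null
#' allele and become "OO". When a null allele segregates, the remaining
#' homozygous calls are recoded as allele plus null (AA -> AO,
#' BB -> BO): a four-cluster AA x BB family is thereby reclassified as
#' AO x BO giving AO, AB, BO and OO progeny. Without a low-size cluster
#' the table is returned unchanged; a marker whose every sample is
#' low-size is degenerate and flagged.
#'
#' @param calls character calls (AA/AB/BB/OTV/NoCall).
#' @return list(calls = recoded vector, degenerate = logical,
#'   null_segregates = logical).
#' @export
otvRecall <- function(calls) {
  is_otv <- calls == "OTV"
  if (!any(is_otv))
    return(list(calls = calls, degenerate = FALSE, null_segregates = FALSE))
  if (all(is_otv))
    return(list(calls = rep("OO", length(calls)), degenerate = TRUE,
                null_segregates = TRUE))
  out <- calls
  out[is_otv] <- "OO"
  out[calls == "AA"] <- "AO"
  out[calls == "BB"] <- "BO"
  list(calls = out, degenerate = FALSE, null_segregates = TRUE)
}

#' Relate read depth to diploid-like clustering
#'
#' Joins per-marker mean read depth (unit-binned from 0 to 150, as in
#' [geneReadDepthProfile()]) with per-marker cluster ploidy patterns, so
#' that technical versus biological ploidy reduction can be told apart:
#' markers inside deletion blocks cluster diploid-like at reduced depth,
#' haploSNPs cluster diploid-like at full depth.
#'
#' @param marker_depth numeric mean read depth per marker.
#' @param ploidy_pattern character "diploid_like"/"polyploid_like" per
#'   marker.
#' @return data.frame(bin, n_markers, frequency, frac_diploid_like).
#' @export
depthVsClustering <- function(marker_depth, ploidy_pattern) {
  stopifnot(length(marker_depth) == length(ploidy_pattern))
  bin <- pmin(floor(marker_depth), 150)
  tab <- table(factor(bin, levels = 0:150))
  dip <- tapply(ploidy_pattern == "diploid_like", factor(bin, levels = 0:150),
                mean)
  data.frame(bin = 0:150, n_markers = as.integer(tab),
             frequency = as.integer(tab) / length(marker_depth),
             frac_diploid_like = as.numeric(dip))
}
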