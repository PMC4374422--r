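test_that("centre and contrast closed forms match hand-computed values", {
  expect_equal(clusterCenter(1, 1), c(A = 200, B = 200))
  expect_equal(clusterCenter(0, 8), c(A = 100, B = 900))
  expect_equal(clusterCenter(0, 0), c(A = 100, B = 100))
  cs <- contrastSize(200, 200)
  expect_equal(cs$contrast, 0)
  expect_equal(contrastSize(200, 800)$contrast, -2)
  expect_equal(contrastSize(300, 300)$contrast, 0)  # 4x AABB
  # all nine octoploid dosage genotypes: A = 100(nA+1), B = 100(nB+1)
  for (nA in 0:8) {
    nB <- 8 - nA
    ab <- clusterCenter(nA, nB)
    expect_equal(unname(ab), c(100 * (nA + 1), 100 * (nB + 1)))
    cs <- contrastSize(ab[1], ab[2])
    expect_equal(cs$contrast, log2((nA + 1) / (nB + 1)))
    expect_equal(cs$size, unname((log2(ab[1]) + log2(ab[2])) / 2))
  }
  expect_error(contrastSize(-1, 100))
})

test_that("HomRO separates diploid-like from polyploid-like patterns", {
  # diploid: AA = (300,100), BB = (100,300)
  cs <- contrastSize(c(300, 100), c(100, 300))
  h <- homro(setNames(cs$contrast, c("AA", "BB")))
  expect_equal(h$value, log2(3), tolerance = 1e-12)
  expect_equal(h$ploidy_pattern, "diploid_like")
  # octoploid B-fixed: marker-AA = (300,700), BB = (100,900)
  cs <- contrastSize(c(300, 100), c(700, 900))
  h <- homro(setNames(cs$contrast, c("AA", "BB")))
  expect_equal(h$value, log2(3 / 7), tolerance = 1e-12)
  expect_equal(h$ploidy_pattern, "polyploid_like")
  # 4x pattern with AABB at contrast 0
  h <- homro(c(AA = 0, AB = -1, BB = -2))
  expect_equal(h$value, 0)
  expect_equal(h$ploidy_pattern, "polyploid_like")
  expect_error(homro(c(AB = 0)), "homozygous")
})

test_that("HomRO sign is invariant over model brightness for 2x and 8x loci", {
  for (int_per_allele in c(50, 100, 400)) {
    m <- clusterCenterModel(int_per_allele, int_per_allele, 100)
    g <- matrix(c("AA", "AB", "BB"), 1, 3,
                dimnames = list("m", c("s1", "s2", "s3")))
    for (p in c(2L, 8L)) {
      d <- generateIntensities(g, p, model = m, noise_sd = 0)
      centers <- setNames(d$contrast, d$genotype)
      h <- homro(centers[c("AA", "BB")])
      if (p == 2L) expect_equal(h$ploidy_pattern, "diploid_like")
      else expect_equal(h$ploidy_pattern, "polyploid_like")
    }
  }
})

test_that("the caller is exact on noise-free data and accurate under noise", {
  g <- matrix(rep(c("AA", "AB", "BB"), each = 100), 1,
              dimnames = list("m", NULL))
  d0 <- generateIntensities(g, 8L, noise_sd = 0)
  cl <- callGenotypes(d0$contrast, d0$size)
  expect_equal(cl$call, d0$genotype)          # 100% correct
  expect_equal(cl$k, 3L)
  # noise_sd = 0.05 at 300 samples: accuracy >= 99%
  dn <- generateIntensities(g, 8L, noise_sd = 0.05, seed = 8)
  cln <- callGenotypes(dn$contrast, dn$size)
  acc <- mean(cln$call == dn$genotype)
  expect_gte(acc, 0.99)
})

test_that("stringent confidence thresholds never decrease NoCalls", {
  set.seed(3)
  x <- c(rnorm(50, -1, 0.3), rnorm(50, 0, 0.3), rnorm(50, 1, 0.3))
  n_nc <- vapply(c(0.15, 0.01), function(th)
    sum(callGenotypes(x, conf_threshold = th)$call == "NoCall"), 1L)
  expect_gte(n_nc[2], n_nc[1])
})

test_that("single-cluster input yields one genotype", {
  cl <- callGenotypes(rep(1.5, 20))
  expect_equal(cl$k, 1L)
  expect_true(all(cl$call == "AA"))
})

test_that("quality classes follow the decision order exactly", {
  base_calls <- rep(c("AA", "AB", "BB"), c(10, 20, 10))
  contr <- rep(c(1, 0, -1), c(10, 20, 10))
  # call rate below 97% -> CRBT even with three clusters
  calls <- base_calls; calls[1:3] <- "NoCall"
  q <- classifyQuality(calls, contr)
  expect_equal(q$class, "CRBT")
  expect_lt(q$call_rate, 0.97)
  # monomorphic -> MHR
  expect_equal(classifyQuality(rep("BB", 40), rep(-1, 40))$class, "MHR")
  # extra low-intensity cluster -> OTV
  calls <- base_calls; calls[1:5] <- "OTV"
  expect_equal(classifyQuality(calls, contr)$class, "OTV")
  # two clusters -> NMH
  expect_equal(classifyQuality(rep(c("AA", "AB"), 20),
                               rep(c(1, 0), 20))$class, "NMH")
  # three clusters, all QC -> filtered PHR
  q <- classifyQuality(base_calls, contr)
  expect_equal(q$class, "PHR")
  expect_true(q$filtered)
})

test_that("PHR post-filters trigger exactly at their thresholds", {
  mk <- function(n_minor) {
    calls <- rep(c("AA", "AB", "BB"), c(n_minor, 25, 15))
    list(calls = calls, contr = rep(c(1, 0, -1), c(n_minor, 25, 15)))
  }
  # minor-homozygote count 2 fails, 3 passes
  q2 <- classifyQuality(mk(2)$calls, mk(2)$contr)
  expect_false(q2$filtered)
  expect_true("nMinorHom" %in% q2$failed_filters)
  q3 <- classifyQuality(mk(3)$calls, mk(3)$contr)
  expect_true(q3$filtered)
  # a discordant technical replicate pair fails reproducibility
  d <- mk(5)
  rp <- cbind(1, 6)   # an AA sample vs an AB sample
  q <- classifyQuality(d$calls, d$contr, replicate_pairs = rp)
  expect_false(q$filtered)
  expect_true("reproducibility" %in% q$failed_filters)
  rp_ok <- cbind(1, 2)
  expect_true(classifyQuality(d$calls, d$contr,
                              replicate_pairs = rp_ok)$filtered)
  expect_error(classifyQuality(d$calls, d$contr,
                               replicate_pairs = cbind(1, 99)),
               "unknown samples")
})

test_that("an inflated heterozygous cluster variance fails AB.varY", {
  calls <- rep(c("AA", "AB", "BB"), c(10, 20, 10))
  contr <- rep(c(1, 0, -1), c(10, 20, 10))
  size <- c(rnorm(10, 8, 0.01), rnorm(20, 8, 2), rnorm(10, 8, 0.01))
  th <- qualityThresholds(ref_var_y = 0.01^2, ref_var_x = NA)
  q <- classifyQuality(calls, contr, size, thresholds = th)
  expect_false(q$filtered)
  expect_true("AB.varY" %in% q$failed_filters)
})

test_that("the classifier is total over randomised inputs", {
  set.seed(9)
  classes <- replicate(60, {
    n <- sample(10:60, 1)
    calls <- sample(c("AA", "AB", "BB", "OTV", "NoCall"), n, TRUE,
                    prob = c(0.3, 0.3, 0.25, 0.05, 0.1))
    classifyQuality(calls, rnorm(n))$class
  })
  expect_true(all(classes %in% c("PHR", "NMH", "OTV", "MHR", "CRBT", "Other")))
})

test_that("OTV recall recodes null alleles and four-cluster families", {
  calls <- c("AA", "AB", "BB", "OTV", "AB")
  r <- otvRecall(calls)
  expect_equal(r$calls, c("AO", "AB", "BO", "OO", "AB"))
  expect_true(r$null_segregates)
  # no low-size cluster: unchanged
  r0 <- otvRecall(c("AA", "AB"))
  expect_identical(r0$calls, c("AA", "AB"))
  # all samples low-size: degenerate
  rd <- otvRecall(rep("OTV", 4))
  expect_true(rd$degenerate)
  # the recoded AA x BB family is AO x BO and its progeny are concordant
  ped <- generatePedigree("AO", "BO", 60, seed = 5)
  cc <- checkConcordance("AO", "BO", ped$progeny)
  expect_true(cc$concordant)
})

test_that("caller and panel classifier recover a simulated OTV cluster", {
  # at 8x the null cluster sits ~2 log2 units below the called clusters
  g <- matrix(rep(c("AA", "AB", "BB", "OO"), each = 40), 1,
              dimnames = list("m", NULL))
  d <- generateIntensities(g, 8L, noise_sd = 0.02, seed = 4)
  cl <- callGenotypes(d$contrast, d$size)
  expect_equal(unname(cl$call[d$genotype == "OO"]), rep("OTV", 40))
  q <- classifyQuality(cl$call, d$contrast, d$size)
  expect_equal(q$class, "OTV")
})

test_that("depth bins join cluster patterns into diploid-like fractions", {
  depth <- c(rep(15, 30), rep(30, 70))
  pattern <- c(rep("diploid_like", 30), rep(c("diploid_like", "polyploid_like"),
                                            c(7, 63)))
  tab <- depthVsClustering(depth, pattern)
  expect_equal(tab$frac_diploid_like[tab$bin == 15], 1.0)
  expect_equal(tab$frac_diploid_like[tab$bin == 30], 0.1)
  expect_equal(sum(tab$n_markers), 100L)
})

test_that("mixture fits agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(12)
  x <- c(rnorm(80, -2, 0.15), rnorm(80, 0, 0.15), rnorm(80, 2, 0.15))
  ours <- callGenotypes(x, k = 3)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  ours_centers <- sort(unname(ours$centers))
  mc_centers <- sort(unname(mc$parameters$mean))
  expect_equal(ours_centers, mc_centers, tolerance = 0.05)
  agree <- mean(as.integer(factor(ours$call, c("BB", "AB", "AA"))) ==
                  mc$classification)
  expect_gte(agree, 0.99)
})
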