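# Chance-corrected partition indices against brute-force enumeration
# oracles.

test_that("pair categories match direct pair enumeration", {
  # identical partitions: no disagreeing pairs
  l <- c(1, 1, 2, 3, 3, 3)
  pc <- pair_counts(partition_pair(l, l))
  expect_equal(unname(pc[c("FD", "FS")]), c(0, 0))

  # the 4-sample crossing example, all 6 pairs enumerated by hand
  pc <- pair_counts(partition_pair(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  expect_equal(pc, c(TS = 0, TD = 2, FD = 2, FS = 2))

  # contingency-table route vs brute enumeration on random labelings
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:20, 1)
    ref <- sample.int(4, n, replace = TRUE)
    obt <- sample.int(3, n, replace = TRUE)
    pp <- partition_pair(ref, obt)
    expect_equal(pp$pair_counts, brute_pair_counts(ref, obt))
    expect_equal(sum(pp$pair_counts), choose(n, 2))
    expect_equal(sort(unname(rowSums(pp$contingency))),
                 sort(as.vector(table(ref))))
  }
})

test_that("Rand index: identical partitions, worked example, relabeling invariance", {
  l <- c(1, 2, 2, 3)
  expect_equal(rand_index(l, l), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2 / 6)
  set.seed(1)
  ref <- sample.int(3, 15, replace = TRUE)
  obt <- sample.int(3, 15, replace = TRUE)
  relab <- c(3, 1, 2)[obt]
  expect_equal(rand_index(ref, relab), rand_index(ref, obt))
})

test_that("Stirling numbers of the second kind are exact", {
  for (n in c(1, 4, 9)) {
    expect_equal(stirling2(n, 1), 1)
    expect_equal(stirling2(n, n), 1)
  }
  expect_equal(stirling2(4, 2), 7)
  # oracle: count the enumerated set partitions directly
  expect_equal(stirling2(10, 3), length(enum_set_partitions(10, 3)))
  expect_equal(stirling2(6, 2), length(enum_set_partitions(6, 2)))
  # far beyond double precision: digits only, spot-check leading digits
  big <- stirling2(300, 3)
  expect_type(big, "character")
  # S(n,3) = (3^(n-1) + 1)/2 - 2^(n-1); its digit count follows from logs
  expect_equal(nchar(big), floor(299 * log10(3) - log10(2)) + 1)
  expect_error(stirling2(3, 5), "C <= n")
})

test_that("the fnc expected Rand index equals the exhaustive-enumeration mean", {
  # n = 6, C = 2: all 31 two-block partitions are equiprobable
  ref <- c(1, 1, 1, 2, 2, 3)
  parts <- enum_set_partitions(6, 2)
  expect_length(parts, 31)
  mean_ri <- mean(vapply(parts, function(p) brute_rand_index(ref, p),
                         numeric(1)))
  expect_equal(expected_rand_fnc(partition_pair(ref, parts[[1]]), C = 2),
               mean_ri, tolerance = 1e-12)
})

test_that("ARI_fnc is 1 on identical partitions and can go negative", {
  l <- rand_labels(12, 3, seed = 2)
  expect_equal(ari_fnc(l, l), 1)
  # anti-aligned partitions fall below the chance level
  expect_equal(ari_fnc(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.4)
})

test_that("ARI_fnc rejects degenerate nulls and mismatched cluster counts", {
  ref <- c(1, 1, 1, 1)
  expect_error(ari_fnc(ref, ref), "undefined")  # C = 1: E_fnc[RI] = 1
  expect_error(ari_fnc(c(1, 1, 2, 2), c(1, 1, 1, 2), C = 3), "premise")
})

test_that("entropies and mutual information match plug-in computation", {
  l <- c(1, 1, 2, 2, 3, 3)
  mi <- mutual_information(l, l)
  expect_equal(mi$H_R, mi$H_O)
  expect_equal(mi$H_RO, mi$H_R)
  expect_equal(mi$MI, mi$H_R)

  # crossed product partition: independent, MI = 0
  ref <- rep(1:2, each = 6)
  obt <- rep(rep(1:3, each = 2), 2)
  expect_equal(mutual_information(ref, obt)$MI, 0)

  for (seed in 1:10) {
    set.seed(seed)
    ref <- sample.int(4, 30, replace = TRUE)
    obt <- sample.int(3, 30, replace = TRUE)
    out <- mutual_information(ref, obt)
    expect_equal(out$MI, mi_plugin(ref, obt), tolerance = 1e-12)
    expect_equal(out$H_R, entropy_plugin(ref), tolerance = 1e-12)
  }
})

test_that("expected MI equals the exhaustive permutation mean", {
  expect_equal(expected_mi(rep(1, 5), rep(1, 5)), 0)  # 1x1 contingency
  # balanced 4-sample case: average over all 4! = 24 label permutations
  ref <- c(1, 1, 2, 2)
  obt <- c(1, 2, 1, 2)
  perm_mean <- mean(vapply(enum_permutations(obt), function(p)
    mi_plugin(ref, p), numeric(1)))
  expect_equal(expected_mi(ref, obt), perm_mean, tolerance = 1e-12)
})

test_that("expected MI never exceeds either entropy", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(6:25, 1)
    ref <- sample.int(3, n, replace = TRUE)
    obt <- sample.int(4, n, replace = TRUE)
    mi <- mutual_information(ref, obt)
    expect_lte(expected_mi(ref, obt), min(mi$H_R, mi$H_O) + 1e-12)
  }
})

test_that("AMI_max is 1 exactly on identical partitions and can dip negative", {
  l <- rand_labels(10, 3, seed = 5)
  expect_equal(ami_max(l, l), 1)
  relab <- c(2, 3, 1)[l]
  expect_equal(ami_max(l, relab), 1)  # identical as partitions
  # zero MI with positive E[MI] is below chance
  expect_lt(ami_max(c(1, 1, 2, 2), c(1, 2, 2, 1)), 0)
})

test_that("both indices are invariant under cluster relabeling and bounded by 1", {
  for (seed in 1:10) {
    ref <- rand_labels(18, 3, seed = seed)
    obt <- rand_labels(18, 3, seed = seed + 100)
    perm <- sample(3)
    expect_equal(ari_fnc(ref, perm[obt]), ari_fnc(ref, obt))
    expect_equal(ami_max(ref, perm[obt]), ami_max(ref, obt))
    expect_lte(ari_fnc(ref, obt), 1)
    expect_lte(ami_max(ref, obt), 1)
    if (!identical(ref, obt)) {
      expect_lt(ari_fnc(ref, obt), 1)
      expect_lt(ami_max(ref, obt), 1)
    }
  }
})

test_that("ARI_fnc and AMI_max rank partitions almost identically", {
  # degrade a fixed reference by flipping ever more labels: the two
  # indices should order the results the same way (near-linear relation)
  ref <- rand_labels(60, 3, seed = 9)
  set.seed(10)
  scores <- t(vapply(seq(0, 40, by = 2), function(k) {
    obt <- ref
    flip <- sample(60, k)
    obt[flip] <- vapply(obt[flip], function(v) sample(setdiff(1:3, v), 1),
                        numeric(1))
    if (length(unique(obt)) < 3) return(c(NA, NA))
    c(ari_fnc(ref, obt), ami_max(ref, obt))
  }, numeric(2)))
  scores <- scores[complete.cases(scores), ]
  expect_gt(cor(scores[, 1], scores[, 2], method = "spearman"), 0.9)
})
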