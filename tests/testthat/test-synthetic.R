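test_that("zero mutation makes chemical series internally identical", {
  syn <- generate_synthetic(synthetic_spec(n_molecules = 40, n_bits = 64,
                                           n_clusters = 4,
                                           mutation_rate = 0, seed = 3,
                                           duplicate_fraction = 0,
                                           salt_fraction = 0))
  S <- similarity_matrix(syn$fingerprints)$values
  cl <- syn$ground_truth$cluster
  for (k in unique(cl)) {
    within <- S[cl == k, cl == k]
    expect_equal(unname(within), matrix(1, sum(cl == k), sum(cl == k)))
  }
})

test_that("with no noise or cliffs the Ki mapping inverts to the clamped activity", {
  syn <- generate_synthetic(synthetic_spec(n_molecules = 50, n_bits = 64,
                                           n_clusters = 4, noise_sd = 0,
                                           cluster_effect_sd = 0,
                                           cliff_fraction = 0, seed = 7,
                                           duplicate_fraction = 0,
                                           salt_fraction = 0))
  y <- syn$ground_truth$y_star
  expect_equal(spki(syn$records$ki_nM), pmin(1, pmax(0, y)),
               tolerance = 1e-12)
})

test_that("the default spec spans and exceeds the clamping interval", {
  syn <- generate_synthetic(synthetic_spec(seed = 1))
  y <- syn$ground_truth$y_star
  v <- spki(syn$records$ki_nM)
  expect_true(any(y < 0) && any(y > 1))
  expect_true(any(v == 0) && any(v == 1))
  expect_true(min(syn$records$ki_nM) < 1 && max(syn$records$ki_nM) > 1e4)
})

test_that("chemical series are more similar within than between", {
  syn <- generate_synthetic(synthetic_spec(seed = 11))
  cl <- syn$ground_truth$cluster
  parents <- syn$ground_truth$mol_id
  S <- similarity_matrix(
    feature_matrix(syn$fingerprints$matrix[parents, ], "bits"))$values
  same <- outer(cl, cl, "==")
  diag(same) <- NA
  within <- mean(S[which(same)])
  between <- mean(S[which(!same)])
  expect_gt(within, between)
})

test_that("an oracle regression on the informative bits certifies the signal", {
  sp <- synthetic_spec(n_molecules = 300, n_bits = 128, n_clusters = 6,
                       noise_sd = 0.02, cluster_effect_sd = 0.02,
                       cliff_fraction = 0, duplicate_fraction = 0,
                       salt_fraction = 0,
                       effect_sizes = c(0.25, 0.2, 0.15, 0.12, 0.08),
                       seed = 13)
  syn <- generate_synthetic(sp)
  bits <- syn$fingerprints$matrix[syn$ground_truth$mol_id,
                                  syn$informative_bits]
  y <- spki(syn$records$ki_nM)
  fit <- lm(y ~ bits)
  expect_gte(summary(fit)$r.squared, 0.9)
})

test_that("duplicates and salts are emitted and survive curation correctly", {
  sp <- synthetic_spec(n_molecules = 100, n_bits = 64, n_clusters = 4,
                       duplicate_fraction = 0.1, salt_fraction = 0.1,
                       seed = 17)
  syn <- generate_synthetic(sp)
  expect_equal(nrow(syn$records), 110)
  expect_equal(sum(grepl("_dup$", syn$records$mol_id)), 10)
  expect_equal(sum(grepl(".", syn$records$smiles, fixed = TRUE)), 11)
  # every record id has a fingerprint row; duplicates share parent bits
  expect_setequal(syn$records$mol_id, syn$fingerprints$mol_ids)
  dup_ids <- grep("_dup$", syn$records$mol_id, value = TRUE)
  for (d in dup_ids[1:3]) {
    expect_equal(syn$fingerprints$matrix[d, ],
                 syn$fingerprints$matrix[sub("_dup$", "", d), ])
  }
  # curation removes exactly the duplicate structures
  cur <- curate(syn$records, canonicalize = "none")
  expect_equal(nrow(cur$records), 100)
  expect_false(any(grepl(".", cur$records$smiles, fixed = TRUE)))
})

test_that("generation is reproducible and validates its spec", {
  s1 <- generate_synthetic(synthetic_spec(n_molecules = 50, n_bits = 32,
                                          n_clusters = 4, seed = 19))
  s2 <- generate_synthetic(synthetic_spec(n_molecules = 50, n_bits = 32,
                                          n_clusters = 4, seed = 19))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$fingerprints$matrix, s2$fingerprints$matrix)
  expect_error(synthetic_spec(n_molecules = 10, n_clusters = 20), "clusters")
  expect_error(synthetic_spec(mutation_rate = 1.5), "\\[0, 1\\]")
  tmp <- file.path(tempdir(), "syn_out")
  paths <- write_synthetic(s1, tmp)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read.csv(paths[1])), nrow(s1$records))
})

test_that("activity cliffs degrade metric-space generalization", {
  pves <- sapply(1:5, function(s) {
    vapply(c(0, 0.3), function(cf) {
      syn <- generate_synthetic(synthetic_spec(
        n_molecules = 150, n_bits = 64, n_clusters = 6,
        cliff_fraction = cf, duplicate_fraction = 0, salt_fraction = 0,
        seed = 100 + s))
      b <- as_qsar_bundle(syn, "d")
      run_single_task(b, "metric_pca", "synthetic_bits",
                      run_config(seed = 200 + s, k_max = 8))$evaluation$ivs_pve
    }, numeric(1))
  })
  expect_lt(median(pves[2, ]), median(pves[1, ]))
})
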