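test_that("spki matches the clamped scaled-pKi definition", {
  expect_identical(spki(10000), 0)
  expect_identical(spki(1), 1)
  expect_equal(spki(100), 0.5)
  expect_identical(spki(50000), 0)
  expect_equal(spki(10), 0.75)
  expect_equal(spki(c(1, 100, 10000)), c(1, 0.5, 0))
  expect_error(spki(0), "positive")
  expect_error(spki(-5), "positive")
  expect_error(spki(NA_real_), "missing")
})

test_that("spki is non-increasing and continuous at both clamp boundaries", {
  ki <- 10^seq(-2, 5, length.out = 5000)
  v <- spki(ki)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v >= 0 & v <= 1))
  # limits from inside the open interval equal the clamp values
  expect_equal(spki(1 + 1e-9), 1, tolerance = 1e-6)
  expect_equal(spki(1e4 * (1 - 1e-9)), 0, tolerance = 1e-6)
})

test_that("curation keeps the most recent duplicate measurement", {
  raw <- data.frame(mol_id = c("x1", "x2"), smiles = c("CCO", "CCO"),
                    ki_nM = c(100, 200), year = c(2009L, 2015L))
  cur <- curate(raw, canonicalize = "none")
  expect_equal(nrow(cur$records), 1)
  expect_equal(cur$records$mol_id, "x2")
  expect_equal(cur$records$year, 2015L)
  expect_true(any(grepl("duplicate", cur$provenance_log)))

  # a record without a year loses the tie to a dated record
  raw2 <- data.frame(mol_id = c("y1", "y2"), smiles = c("CCO", "CCO"),
                     ki_nM = c(100, 200), year = c(NA, 1999L))
  expect_equal(curate(raw2, canonicalize = "none")$records$mol_id, "y2")

  # equal years: the later input row wins
  raw3 <- data.frame(mol_id = c("z1", "z2"), smiles = c("CCO", "CCO"),
                     ki_nM = c(100, 200), year = c(2010L, 2010L))
  expect_equal(curate(raw3, canonicalize = "none")$records$mol_id, "z2")
})

test_that("multi-fragment structures are reduced to the largest fragment", {
  raw <- data.frame(mol_id = "s1", smiles = "CCCCCC.[Na+]",
                    ki_nM = 10, year = 2010L)
  cur <- curate(raw, canonicalize = "none")
  expect_equal(cur$records$smiles, "CCCCCC")
  expect_true(any(grepl("fragment", cur$provenance_log)))
  # two-letter symbols and bracket atoms are counted correctly
  expect_equal(metricqsar:::heavy_atom_count("ClCCl"), 3)
  expect_equal(metricqsar:::heavy_atom_count("[Na+]"), 1)
  expect_equal(metricqsar:::heavy_atom_count("[nH]1cccc1"), 5)
  expect_equal(metricqsar:::largest_fragment("CC.CCCBr"), "CCCBr")
})

test_that("clean input passes through unchanged and curation is idempotent", {
  raw <- toy_records()
  cur <- curate(raw, canonicalize = "none")
  expect_equal(cur$records$mol_id, raw$mol_id)
  expect_equal(cur$records$smiles, raw$smiles)
  twice <- curate(cur$records[, names(raw)], canonicalize = "none")
  expect_equal(twice$records[, names(raw)], cur$records[, names(raw)])
})

test_that("records with missing activity or structure are dropped, empty output errors", {
  raw <- data.frame(mol_id = c("a", "b", "c"), smiles = c("CCO", "", "CCC"),
                    ki_nM = c(NA, 10, 20), year = 2010L)
  cur <- curate(raw, canonicalize = "none")
  expect_equal(cur$records$mol_id, "c")
  bad <- data.frame(mol_id = "a", smiles = "CCO", ki_nM = NA_real_,
                    year = 2010L)
  expect_error(curate(bad, canonicalize = "none"), "no usable records")
})

test_that("openbabel canonicalization unifies equivalent SMILES", {
  skip_if_not(toolkit_available())
  raw <- data.frame(mol_id = c("b1", "b2"),
                    smiles = c("C1=CC=CC=C1", "c1ccccc1"),
                    ki_nM = c(10, 20), year = c(2001L, 2005L))
  cur <- curate(raw, canonicalize = "openbabel")
  expect_equal(nrow(cur$records), 1)
  expect_equal(cur$records$mol_id, "b2")
  # unparseable structures are dropped with a logged reason, not an error
  raw2 <- data.frame(mol_id = c("ok", "bad"), smiles = c("CCO", "xq%%"),
                     ki_nM = c(10, 20), year = 2010L)
  cur2 <- curate(raw2, canonicalize = "openbabel")
  expect_equal(cur2$records$mol_id, "ok")
  expect_true(any(grepl("unparseable", cur2$provenance_log)))
})

test_that("train/IVS split is seeded, disjoint, and order-independent", {
  syn <- generate_synthetic(synthetic_spec(n_molecules = 100, n_bits = 32,
                                           n_clusters = 4, seed = 5,
                                           duplicate_fraction = 0,
                                           salt_fraction = 0))
  cur <- curate(syn$records, canonicalize = "none")
  s1 <- split_dataset(cur, 0.2, seed = 11)
  s2 <- split_dataset(cur, 0.2, seed = 11)
  expect_equal(sum(s1$split == "ivs"), 20)
  expect_equal(sum(s1$split == "train"), 80)
  expect_identical(s1$split, s2$split)
  # union is the curated set, intersection empty
  expect_setequal(c(which(s1$split == "train"), which(s1$split == "ivs")),
                  seq_len(100))
  # permuted input order, same seed -> same partition by mol_id
  perm <- sample(nrow(cur$records))
  curp <- cur
  curp$records <- cur$records[perm, ]
  s3 <- split_dataset(curp, 0.2, seed = 11)
  expect_setequal(curp$records$mol_id[s3$split == "ivs"],
                  cur$records$mol_id[s1$split == "ivs"])
  # different seed -> (almost surely) different partition
  s4 <- split_dataset(cur, 0.2, seed = 12)
  expect_false(identical(s1$split, s4$split))
})

test_that("degenerate split fractions error", {
  cur <- curate(toy_records(), canonicalize = "none")
  expect_error(split_dataset(cur, 0.2), "at least 10")
  syn <- generate_synthetic(synthetic_spec(n_molecules = 100, n_bits = 32,
                                           n_clusters = 4, seed = 5))
  cur2 <- curate(syn$records, canonicalize = "none")
  expect_error(split_dataset(cur2, 0.999), "fewer than 2")
  expect_error(split_dataset(cur2, 1.2), "ivs_fraction")
})

test_that("curated CSV round-trips through the writers", {
  syn <- generate_synthetic(synthetic_spec(n_molecules = 60, n_bits = 32,
                                           n_clusters = 3, seed = 2))
  cur <- split_dataset(curate(syn$records, canonicalize = "none"), 0.2, 1)
  tmp <- file.path(tempdir(), "curated.csv")
  write_curated_csv(cur, tmp)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$mol_id, cur$records$mol_id)
  expect_equal(back$split, cur$split)
  expect_true(file.exists(sub("\\.csv$", ".provenance.json", tmp)))
  raw <- read_molecule_csv(tmp)
  expect_true(all(c("mol_id", "smiles", "ki_nM") %in% names(raw)))
})
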