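# Binding-site definition and the nine-bit interaction fingerprint

test_that("site inclusion respects the distance cutoff boundary", {
  tc <- make_toy_complex(residues = c("PHE", "SER"), n_chains = 1,
                         ligand_atoms = data.frame(element = "C", chain = "A",
                                                   res_index = 1, atom = "CA",
                                                   distance = 8.9))
  site <- define_binding_site(tc$receptor, tc$pose, cutoff_A = 9)
  expect_true(551 %in% site$resno)
  # a residue whose nearest atom is beyond the cutoff stays out
  far <- make_toy_complex(residues = c("PHE", "SER"), n_chains = 1, spacing = 30,
                          ligand_atoms = data.frame(element = "C", chain = "A",
                                                    res_index = 1, atom = "CA",
                                                    distance = 2))
  site_far <- define_binding_site(far$receptor, far$pose, cutoff_A = 9)
  expect_false(552 %in% site_far$resno)
})

test_that("a pose outside the receptor is an error", {
  tc <- make_toy_complex(ligand_atoms = data.frame(element = "C", x = 500,
                                                   y = 500, z = 500))
  expect_error(define_binding_site(tc$receptor, tc$pose), "outside")
})

test_that("monomer copies collapse to one residue key", {
  tc <- make_toy_complex(residues = "PHE", n_chains = 4,
                         ligand_atoms = data.frame(element = "C", chain = "A",
                                                   res_index = 1, atom = "CZ",
                                                   distance = 3))
  site <- define_binding_site(tc$receptor, tc$pose, cutoff_A = 9)
  expect_equal(nrow(site[site$resno == 551, ]), 1L)
  expect_equal(site$resid[site$resno == 551], "PHE")
})

test_that("a hydrophobic aromatic side-chain contact sets the documented bits", {
  tc <- make_toy_complex(residues = "PHE", n_chains = 1,
                         ligand_atoms = data.frame(element = "C", chain = "A",
                                                   res_index = 1, atom = "CZ",
                                                   distance = 3.5))
  site <- define_binding_site(tc$receptor, tc$pose)
  fp <- compute_fingerprint(tc$receptor, tc$pose, site)
  row <- fp["551_PHE", ]
  expect_equal(unname(row[c("contact", "sidechain", "hydrophobic", "aromatic")]),
               rep(1L, 4))
  expect_equal(unname(row[c("polar", "charged", "hbond_acceptor", "hbond_donor")]),
               rep(0L, 4))
  # CZ at 3.5 A; the backbone is > 4.5 A away in this construction
  expect_equal(unname(row["backbone"]), 0L)
})

test_that("a residue out of contact range has all nine bits zero", {
  tc <- make_toy_complex(residues = c("PHE", "SER", "ALA"), n_chains = 1,
                         ligand_atoms = data.frame(element = "C", chain = "A",
                                                   res_index = 1, atom = "CZ",
                                                   distance = 3.0))
  site <- define_binding_site(tc$receptor, tc$pose, cutoff_A = 20)
  fp <- compute_fingerprint(tc$receptor, tc$pose, site)
  expect_true(all(fp["553_ALA", ] == 0L))
})

test_that("an interaction in a single monomer switches the merged bit on", {
  tc <- make_toy_complex(residues = "PHE", n_chains = 4,
                         ligand_atoms = data.frame(element = "C", chain = "C",
                                                   res_index = 1, atom = "CZ",
                                                   distance = 3.2))
  site <- define_binding_site(tc$receptor, tc$pose, cutoff_A = 30)
  fp <- compute_fingerprint(tc$receptor, tc$pose, site)
  expect_equal(unname(fp["551_PHE", "contact"]), 1L)
  # and the tetramer fingerprint equals the OR of per-monomer fingerprints
  per_chain <- lapply(c("A", "B", "C", "D"), function(ch) {
    rec1 <- tc$receptor[tc$receptor$chain == ch, , drop = FALSE]
    compute_fingerprint(rec1, tc$pose, site)
  })
  merged <- Reduce(function(a, b) (a | b) * 1L, lapply(per_chain, unclass))
  expect_equal(unclass(fp), merged, ignore_attr = TRUE)
})

test_that("hydrogen-bond bits follow donor/acceptor typing", {
  # ligand N+ donor 2.9 A from SER OG (acceptor+donor side-chain atom)
  tc <- make_toy_complex(residues = "SER", n_chains = 1,
                         ligand_atoms = data.frame(element = "N", chain = "A",
                                                   res_index = 1, atom = "OG",
                                                   distance = 2.9, charge = 1,
                                                   n_H = 3))
  site <- define_binding_site(tc$receptor, tc$pose)
  fp <- compute_fingerprint(tc$receptor, tc$pose, site)
  expect_equal(unname(fp["551_SER", "hbond_acceptor"]), 1L)
  # a carbon at the same distance makes contact but no H-bond
  tc2 <- make_toy_complex(residues = "SER", n_chains = 1,
                          ligand_atoms = data.frame(element = "C", chain = "A",
                                                    res_index = 1, atom = "OG",
                                                    distance = 2.9))
  fp2 <- compute_fingerprint(tc2$receptor, tc2$pose, site)
  expect_equal(unname(fp2["551_SER", "hbond_acceptor"]), 0L)
  expect_equal(unname(fp2["551_SER", "contact"]), 1L)
})

test_that("fingerprints agree with the brute-force oracle on random complexes", {
  rules <- geometry_rules()
  n_checked <- 0
  for (seed in 1:25) {
    tc <- random_complex(seed)
    site <- tryCatch(define_binding_site(tc$receptor, tc$pose),
                     error = function(e) NULL)
    if (is.null(site)) next
    fp <- compute_fingerprint(tc$receptor, tc$pose, site, rules)
    expect_equal(unclass(fp), oracle_fingerprint(tc$receptor, tc$pose, site, rules),
                 ignore_attr = TRUE)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("fingerprints are invariant under rigid motion of the whole complex", {
  tc <- random_complex(99)
  site <- define_binding_site(tc$receptor, tc$pose)
  fp0 <- compute_fingerprint(tc$receptor, tc$pose, site)
  shift <- c(13.7, -8.2, 4.4)
  rec2 <- tc$receptor
  rec2[, c("x", "y", "z")] <- rotate_translate(rec2[, c("x", "y", "z")], 0.83, shift)
  pose2 <- tc$pose
  pose2$atoms[, c("x", "y", "z")] <-
    rotate_translate(pose2$atoms[, c("x", "y", "z")], 0.83, shift)
  fp1 <- compute_fingerprint(rec2, pose2, site)
  expect_equal(unclass(fp0), unclass(fp1), ignore_attr = TRUE)
})

test_that("enlarging the contact cutoff only turns bits on", {
  for (seed in c(7, 21)) {
    tc <- random_complex(seed)
    site <- tryCatch(define_binding_site(tc$receptor, tc$pose, cutoff_A = 15),
                     error = function(e) NULL)
    if (is.null(site)) next
    fp_small <- compute_fingerprint(tc$receptor, tc$pose, site,
                                    geometry_rules(contact_max_A = 3.5))
    fp_big <- compute_fingerprint(tc$receptor, tc$pose, site,
                                  geometry_rules(contact_max_A = 6.0))
    expect_true(all(fp_big >= fp_small))
  }
})

test_that("every specific interaction implies the contact bit", {
  for (seed in 31:40) {
    tc <- random_complex(seed)
    site <- tryCatch(define_binding_site(tc$receptor, tc$pose),
                     error = function(e) NULL)
    if (is.null(site)) next
    fp <- compute_fingerprint(tc$receptor, tc$pose, site)
    specific <- fp[, setdiff(colnames(fp), "contact"), drop = FALSE]
    expect_true(all(rowSums(specific) == 0 | fp[, "contact"] == 1))
  }
})

test_that("the fingerprint table has deterministic shape and labels", {
  tc <- make_toy_complex(residues = c("PHE", "SER", "ALA"), n_chains = 2)
  site <- define_binding_site(tc$receptor, tc$pose, cutoff_A = 25)
  expect_equal(nrow(site), 3L)
  pose2 <- tc$pose; pose2$compound_id <- "LIG2"
  m <- fingerprint_matrix(tc$receptor, list(tc$pose, pose2), site)
  expect_equal(dim(m), c(2L, 27L))
  expect_true(all(m %in% 0:1))
  expect_equal(m[1, ], m[2, ], ignore_attr = TRUE)   # same pose, same bits
  expect_true("551_aromatic" %in% colnames(m))
  expect_equal(colnames(m)[1:9], paste0("551_", IF_TYPES))
  expect_error(fingerprint_matrix(tc$receptor, list(tc$pose, tc$pose), site),
               "duplicate")
  # CSV round-trip
  tf <- tempfile(fileext = ".csv")
  write_fingerprints(m, tf, site = site, rules = geometry_rules())
  expect_equal(read_fingerprints(tf), m)
  expect_true(file.exists(paste0(tf, ".manifest.json")))
})
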