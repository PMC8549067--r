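test_that("Table geometry defaults are exact and form-specific", {
  b <- na_geometry("bdna")
  expect_identical(b$rise_per_bp, 3.365)
  expect_identical(b$twist_per_bp, 36)
  expect_identical(b$c1_sequential_distance, 4.95)
  expect_identical(b$c1_paired_distance, 10.8)
  a <- na_geometry("arna")
  expect_identical(a$twist_per_bp, 36.787)
  expect_identical(a$c1_sequential_distance, 5.33)
  expect_identical(a$c1_paired_distance, 12.68)
  expect_identical(a$angle_c1_c1_c1, 150.108)
})

test_that("dot-bracket parsing pairs brackets and rejects imbalance", {
  p <- parse_dotbracket("((..))")
  expect_equal(p, c(6L, 5L, NA, NA, 2L, 1L))
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "invalid")
})

test_that("single-strand builder places one 0.5 A atom per nucleotide", {
  ss <- build_pet_ss("ACGU", form = "arna", seed = 1)
  expect_equal(nrow(ss$atoms), 4)
  expect_true(all(ss$atoms$element == "O5"))
  expect_true(all(ss$atoms$radius == 0.5))
  expect_true(all(ss$atoms$bfactor > 0))
  expect_equal(nrow(ss$bonds), 3)
  d <- as.matrix(dist(xyz_of(ss)))
  expect_equal(unname(d[cbind(1:3, 2:4)]), rep(0.533, 3), tolerance = 1e-9)
  expect_error(build_pet_ss("ACGX"), "non-ACGTU")
})

test_that("hairpin dot-bracket adds one pairing bond per bracket pair", {
  hp <- build_pet_ss("GGGGAAAACCCC", "((((....))))", form = "arna", seed = 2)
  pairing_bonds <- hp$bonds[abs(hp$bonds[, 1] - hp$bonds[, 2]) > 1, ,
                            drop = FALSE]
  expect_equal(nrow(pairing_bonds), 4)
  expect_equal(nrow(hp$bonds), 11 + 4)
  # identical seed reproduces the walk bitwise
  hp2 <- build_pet_ss("GGGGAAAACCCC", "((((....))))", form = "arna", seed = 2)
  expect_identical(hp$atoms, hp2$atoms)
  # self-avoidance: non-bonded atom pairs keep their distance floor
  d <- as.matrix(dist(xyz_of(hp)))
  nb <- d[abs(row(d) - col(d)) > 1 & upper.tri(d)]
  expect_gte(min(nb), 0.4 - 1e-9)
})

test_that("double-strand builder uses one main+helper pair per bp triplet", {
  dsx <- build_pet_ds(strrep("A", 30), form = "bdna")
  expect_equal(nrow(dsx$atoms), 2 * 10)
  m <- xyz_of(dsx)
  mains <- seq(1, 19, by = 2)
  expect_equal(unname(sqrt(rowSums((m[mains[-1], ] - m[mains[-10], ])^2))),
               rep(1.0095, 9), tolerance = 1e-9)
  helper_d <- sqrt(rowSums((m[mains + 1, ] - m[mains, ])^2))
  expect_equal(unname(helper_d), rep(1.2, 10), tolerance = 1e-12)
  # helper tracks the backbone: rotation of 3 x twist between neighbours
  v1 <- m[2, ] - m[1, ]; v2 <- m[4, ] - m[3, ]
  ang <- acos(sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
  expect_equal(ang * 180 / pi, 108, tolerance = 1e-6)
  expect_equal(nrow(build_pet_ds("ACG")$atoms), 2)
  expect_error(build_pet_ds("AC"), "at least 3")
})

test_that("double-strand detection needs equal, close, anti-parallel strands", {
  geom <- na_geometry("bdna")
  ideal <- petworld:::ideal_ds_c1(geom, 12)
  s1 <- ideal$strand1 * 0.1
  s2 <- ideal$strand2 * 0.1
  mk <- function(a, b, resno_b = 13:24) {
    atoms <- atom_table("O5", rbind(a, b), elety = "C1P",
                        resno = c(1:12, resno_b),
                        chain = rep(c("A", "B"), each = 12))
    molecular_object("na", atoms, kind = "pet")
  }
  # paired order: strand2 must be stored anti-parallel (3'->5' reversed)
  obj <- mk(s1, s2[12:1, ])
  hits <- detect_double_strand(obj, scale = "pet")
  expect_equal(length(hits), 1)
  # the paired distances are below the 1.2 A pet-scale threshold
  d <- sqrt(rowSums((s1 - s2)^2))
  expect_true(all(d < 1.2))
  # parallel copy fails
  expect_equal(length(detect_double_strand(mk(s1, s2), scale = "pet")), 0)
  # unequal lengths fail
  atoms <- atom_table("O5", rbind(s1, s2[12:3, ]), elety = "C1P",
                      resno = c(1:12, 13:22),
                      chain = rep(c("A", "B"), c(12, 10)))
  obj3 <- molecular_object("na", atoms, kind = "pet")
  expect_equal(length(detect_double_strand(obj3, scale = "pet")), 0)
})

test_that("ideal B-DNA duplexes are classified ds at every length", {
  for (n in c(3, 12, 30, 300)) {
    ideal <- petworld:::ideal_ds_c1(na_geometry("bdna"), n)
    atoms <- atom_table("O5", rbind(ideal$strand1, ideal$strand2[n:1, ]) * 0.1,
                        elety = "C1P", resno = c(1:n, n + 1:n),
                        chain = rep(c("A", "B"), each = n))
    obj <- molecular_object("na", atoms, kind = "pet")
    expect_equal(length(detect_double_strand(obj, scale = "pet")), 1)
  }
  # the A-RNA paired C1*-C1* distance (12.68 A, 1.268 A pet) exceeds the
  # 1.2 A pet-scale criterion, so the distance rule as defined does not
  # fire on an ideal A-form duplex
  ideal <- petworld:::ideal_ds_c1(na_geometry("arna"), 12)
  atoms <- atom_table("O5", rbind(ideal$strand1, ideal$strand2[12:1, ]) * 0.1,
                      elety = "C1P", resno = c(1:12, 13:24),
                      chain = rep(c("A", "B"), each = 12))
  obj <- molecular_object("na", atoms, kind = "pet")
  expect_equal(length(detect_double_strand(obj, scale = "pet")), 0)
})

test_that("genome assembly copies binders per site and stays connected", {
  b <- build_pet_ss("ACGT", form = "bdna", seed = 3)
  b$na_range <- 1:4
  binders <- list(list(site = "ACGT", object = b))
  gen <- assemble_pet_genome(strrep("ACGTTTTT", 3), binders, seed = 4)
  expect_equal(length(gen$instances), 2)       # chain + binder
  expect_equal(length(gen$instances[[2]]), 3)  # 3 occurrences
  chain <- gen$objects[[1]]
  expect_equal(nrow(chain$atoms), 24)          # one atom per nucleotide
  comp <- petworld:::bond_components(nrow(chain$atoms), chain$bonds)
  expect_equal(length(unique(comp)), 1)
  # no occurrences: a pure free chain
  gen0 <- assemble_pet_genome("TTTTTTTT", binders, seed = 5)
  expect_equal(length(gen0$objects), 1)
  expect_equal(nrow(gen0$objects[[1]]$atoms), 8)
})

test_that("single-strand expansion anchors every nucleotide at its pet atom", {
  seq <- make_random_sequence(40, "dna", seed = 6)
  ss <- build_pet_ss(seq, form = "bdna", seed = 6)
  full <- expand_ss(ss)
  expect_equal(full$kind, "nucleic")
  nts <- table(full$atoms$resno)
  expect_equal(length(nts), 40)
  # sequence and length preserved
  expect_equal(paste(full$residues$name, collapse = ""), seq)
  c1 <- xyz_of(full)[full$atoms$elety == "C1*", ]
  expect_lt(max(sqrt(rowSums((c1 - xyz_of(ss) * 10)^2))), 0.01)
  # three-point superposition: N3 and C6 land on their frame targets
  tpl <- na_templates()
  i <- 5
  Fr <- petworld:::c1_local_frame(xyz_of(ss) * 10, i)
  res_atoms <- full$atoms[full$atoms$resno == i, ]
  loc <- function(df, nm) as.numeric(df[df$elety == nm, c("x", "y", "z")])
  tpl_i <- tpl[[substr(seq, i, i)]]
  tloc <- function(nm) as.numeric(tpl_i[tpl_i$name == nm, c("x", "y", "z")])
  target_n3 <- xyz_of(ss)[i, ] * 10 + as.vector(Fr %*% tloc("N3"))
  expect_lt(sqrt(sum((loc(res_atoms, "N3") - target_n3)^2)), 0.1)
})

test_that("backbone junction gaps close below 2 A for a 50-nt random coil", {
  ss <- build_pet_ss(make_random_sequence(50, "dna", seed = 8), seed = 8)
  full <- expand_ss(ss)
  o3 <- xyz_of(full)[full$atoms$elety == "O3*", ]
  p <- xyz_of(full)[full$atoms$elety == "P", ]
  gaps <- sqrt(rowSums((o3[-50, ] - p[-1, ])^2))
  expect_gte(mean(gaps <= 2.0), 0.95)
})

test_that("one-joint CCD matches the closed-form optimum", {
  # planar toy: rotate P about the z axis through b to hit a target ring
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1))
  target <- c(-1.3, 1.1, 1)
  out <- ccd_close_gap(pts, list(list(axis = c(1, 2), moving = 3)),
                       moving_point = 3, target_point = target,
                       target_dist = 0, tol = 1e-9, max_sweeps = 5)
  # closed form: the optimal angle points the moving arm at the target
  th_opt <- atan2(target[2], target[1])
  th_got <- atan2(out$points[3, 2], out$points[3, 1])
  expect_equal(th_got, th_opt, tolerance = 1e-6)
  # zero gap: untouched chain, zero sweeps
  out0 <- ccd_close_gap(pts, list(list(axis = c(1, 2), moving = 3)),
                        moving_point = 3, target_point = c(1, 0, 1),
                        target_dist = 0)
  expect_equal(out0$sweeps, 0)
  expect_identical(out0$points, pts)
})

test_that("CCD never increases the gap across random configurations", {
  set.seed(99)
  worse <- 0
  for (rep in 1:100) {
    pts <- matrix(rnorm(15), 5, 3)
    torsions <- list(list(axis = c(1, 2), moving = 3:5),
                     list(axis = c(2, 3), moving = 4:5),
                     list(axis = c(3, 4), moving = 5))
    target <- rnorm(3) * 2
    out <- ccd_close_gap(pts, torsions, moving_point = 5,
                         target_point = target, target_dist = 0.5)
    if (out$gap > out$gaps[1] + 1e-9) worse <- worse + 1
    expect_true(all(diff(out$gaps) <= 1e-9))
  }
  expect_equal(worse, 0)
})
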