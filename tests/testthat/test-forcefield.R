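test_that("defaults define 12 equal-mass atom types and AMBER constants", {
  ff <- ff_defaults()
  expect_equal(nrow(ff$types), 12)
  expect_equal(ff$types$type, tolower(ff$types$symbol))
  expect_equal(ff$bond_k, 575)
  expect_equal(ff$angle_k, 300)
  expect_equal(ff$dihedral_pk, 5)
  expect_equal(ff$mass, 8)
  expect_equal(ff$cutoff, 3)
  expect_equal(c(ff$dt_bonded, ff$dt_nonbonded), c(0.5, 1))
})

test_that("sequence-built nucleic equilibria come from the geometry table", {
  ss <- build_pet_ss("ACGTAC", form = "bdna", seed = 1)
  terms <- assign_parameters(ss)
  expect_equal(unique(terms$bonds$r0) * 10, 4.95)
  expect_true(all(terms$bonds$k == 575))
  expect_equal(unique(terms$angles$theta0) * 180 / pi, 153.795,
               tolerance = 1e-9)
  # hairpin pairing bond: A-RNA paired C1*-C1* distance
  hp <- build_pet_ss("GGGGAAAACCCC", "((((....))))", form = "arna", seed = 2)
  th <- assign_parameters(hp)
  pair <- th$bonds[abs(th$bonds$i - th$bonds$j) > 1, ]
  expect_equal(unique(pair$r0) * 10, 12.68)
  # ds axis: helper offset bond and the two 90-degree angle replacement
  dsx <- build_pet_ds(strrep("A", 30))
  td <- assign_parameters(dsx)
  helper_bonds <- td$bonds[td$bonds$r0 == 1.2, ]
  expect_equal(nrow(helper_bonds), 10)
  expect_true(all(abs(td$angles$theta0 - pi / 2) < 1e-12))
  expect_equal(nrow(td$angles), 18)  # 2 per interior main, 1 per end
  # helper-main-main-helper dihedral equilibrium = 3 x twist
  expect_equal(unique(td$dihedrals$phase) * 180 / pi - 180, 108,
               tolerance = 1e-9)
})

test_that("no angle terms inside 3-rings, two inside 4-rings", {
  xyz3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.9, 0))
  tri <- molecular_object("t", atom_table(rep("O5", 3), xyz3),
                          rbind(c(1, 2), c(2, 3), c(1, 3)), kind = "pet")
  t3 <- assign_parameters(tri)
  expect_equal(nrow(t3$bonds), 3)
  expect_equal(nrow(t3$angles), 0)
  xyz4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq <- molecular_object("s", atom_table(rep("O5", 4), xyz4),
                         rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                         kind = "pet")
  t4 <- assign_parameters(sq)
  expect_equal(nrow(t4$angles), 2)
  # the two kept terms are neighbouring (their centres are bonded)
  ctr <- sort(t4$angles$j)
  expect_true(any(apply(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 1,
                        function(b) all(sort(b) == ctr))))
})

test_that("ring and angle-window rules hold on random bond graphs", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    xyz <- matrix(rnorm(3 * n, sd = 1.2), n, 3)
    # random connected graph
    bonds <- cbind(1:(n - 1), 2:n)
    extra <- t(combn(n, 2))
    extra <- extra[sample(nrow(extra), n %/% 2), , drop = FALSE]
    bonds <- unique(rbind(bonds, extra))
    obj <- molecular_object("r", atom_table(rep("O5", n), xyz, bfactor = 0),
                           bonds, kind = "pet")
    terms <- assign_parameters(obj)
    bonded <- matrix(FALSE, n, n)
    bonded[rbind(obj$bonds, obj$bonds[, 2:1])] <- TRUE
    if (nrow(terms$angles)) for (r in seq_len(nrow(terms$angles))) {
      a <- terms$angles[r, ]
      expect_false(bonded[a$i, a$k])  # never inside a 3-ring
      expect_gte(a$theta0 * 180 / pi, 20)
      expect_lte(a$theta0 * 180 / pi, 160)
    }
    if (nrow(terms$dihedrals)) for (r in seq_len(nrow(terms$dihedrals))) {
      d <- terms$dihedrals[r, ]
      deg <- table(factor(c(obj$bonds), levels = 1:n))
      # the recipe: A under four bonds, B exactly two (in one orientation)
      okAB <- deg[d$i] < 4 && deg[d$j] == 2
      okDC <- deg[d$l] < 4 && deg[d$k] == 2
      expect_true(okAB || okDC)
    }
    # bonded energy at construction is zero for B = 0 molecules
    e <- evaluate_energy(obj, terms)
    expect_lt(abs(e$bond + e$angle + e$dihedral), 1e-8)
  }
})

test_that("energy evaluation matches an independent naive evaluator", {
  set.seed(23)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(15, sd = 1.5), 5, 3)
    obj <- molecular_object("m", atom_table(rep("O8", 5), xyz,
                                            charge = runif(5, -0.2, 0.2)),
                            rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                            kind = "pet")
    terms <- assign_parameters(obj)
    # evaluate away from construction so every term contributes
    obj$atoms[, c("x", "y", "z")] <- xyz + matrix(rnorm(15, 0, 0.3), 5, 3)
    e <- evaluate_energy(obj, terms)
    expect_equal(e$total, naive_energy(obj$atoms, terms), tolerance = 1e-9)
  }
})

test_that("a stretched pet bond stores 575 delta^2 kcal/mol", {
  at <- atom_table(c("O5", "O5"), rbind(c(0, 0, 0), c(1.0, 0, 0)))
  dimer <- molecular_object("d", at, rbind(c(1, 2)), kind = "pet")
  terms <- assign_parameters(dimer)
  expect_equal(terms$bonds$r0, 1.0)
  # at equilibrium: zero
  expect_equal(evaluate_energy(dimer, terms)$bond, 0)
  dimer$atoms$x[2] <- 1.1
  expect_equal(evaluate_energy(dimer, terms)$bond, 575 * 0.1^2,
               tolerance = 1e-9)
})

test_that("nonbonded terms exclude 1-2/1-3 pairs and the cutoff", {
  xyz <- rbind(c(0, 0, 0), c(0.9, 0, 0), c(1.8, 0, 0), c(10, 0, 0))
  obj <- molecular_object("m", atom_table(rep("O5", 4), xyz,
                                          charge = 0.1),
                          rbind(c(1, 2), c(2, 3), c(3, 4)), kind = "pet")
  terms <- assign_parameters(obj)
  ex <- terms$excluded_pairs
  expect_true(all(apply(rbind(c(1, 2), c(2, 3), c(1, 3)), 1, function(p)
    any(ex[, 1] == p[1] & ex[, 2] == p[2]))))
  # atom 4 is beyond the 3 A cutoff from everything: no nonbonded energy
  e <- evaluate_energy(obj, terms)
  expect_equal(e$vdw, 0)
  expect_equal(e$coulomb, 0)
})

test_that("total pet charge is one tenth of the all-atom charge", {
  cl <- make_globular_cloud(200, seed = 12)
  pet <- shrink_molecule(cl)
  expect_equal(sum(pet$atoms$charge), 0.1 * sum(cl$atoms$charge),
               tolerance = 1e-12)
})

test_that("minimization is monotone and restores a perturbed dimer bond", {
  at <- atom_table(c("O5", "O5"), rbind(c(0, 0, 0), c(0.7, 0, 0)))
  dimer <- molecular_object("d", at, rbind(c(1, 2)), kind = "pet")
  terms <- assign_parameters(dimer)
  terms$bonds$r0 <- 0.5
  out <- minimize_or_integrate(dimer, terms, "minimize", steps = 500)
  expect_true(all(diff(out$energies) <= 1e-12))
  expect_equal(sqrt(sum((out$xyz[1, ] - out$xyz[2, ])^2)), 0.5,
               tolerance = 1e-4)
  # at equilibrium nothing moves
  dimer$atoms$x[2] <- 0.5
  out0 <- minimize_or_integrate(dimer, terms, "minimize", steps = 10)
  expect_equal(out0$xyz, xyz_of(dimer), tolerance = 1e-12)
})

test_that("multiple-time-step NVE dynamics conserves energy", {
  ss <- build_pet_ss(make_random_sequence(12, "dna", 31), seed = 31)
  terms <- assign_parameters(ss)
  mn <- minimize_or_integrate(ss, terms, "minimize", steps = 400)
  ss$atoms[, c("x", "y", "z")] <- mn$xyz
  md <- minimize_or_integrate(ss, terms, "md", steps = 600, seed = 1,
                              temperature = 50)
  e <- md$energies
  drift <- abs(mean(tail(e, 100)) - mean(head(e, 100)))
  expect_lt(drift, 0.01 * mean(md$kinetic))
})
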