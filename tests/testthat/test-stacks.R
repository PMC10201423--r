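test_that("superposition recovers exact transforms and the identity", {
  set.seed(1)
  pts <- matrix(rnorm(18, sd = 4), 6, 3)
  s0 <- superpose(pts, pts)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tgt <- sweep(pts %*% t(R), 2, c(1, 2, 3), "+")
  s1 <- superpose(pts, tgt)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(s1$rotation, R, tolerance = 1e-9)
  expect_equal(s1$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(sweep(pts %*% t(s1$rotation), 2, s1$translation, "+"), tgt,
               tolerance = 1e-9)
})

test_that("superposition matches the quaternion oracle on random instances", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    X <- matrix(rnorm(3 * n, sd = 5), n, 3)
    Y <- matrix(rnorm(3 * n, sd = 5), n, 3)
    expect_equal(superpose(X, Y)$rmsd, quat_rmsd(X, Y), tolerance = 1e-6)
  }
  # the worked perturbation case: fixed 4-point sets, one coordinate moved
  X <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(0, 3, 3))
  Y <- X; Y[2, 1] <- Y[2, 1] + 1
  expect_equal(superpose(X, Y)$rmsd, quat_rmsd(X, Y), tolerance = 1e-6)
})

test_that("rmsd is invariant to rigid motion of either input", {
  set.seed(21)
  X <- matrix(rnorm(24, sd = 5), 8, 3)
  Y <- matrix(rnorm(24, sd = 5), 8, 3)
  base <- superpose(X, Y)$rmsd
  for (rep in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 20)
    expect_equal(superpose(sweep(X %*% t(R), 2, tr, "+"), Y)$rmsd, base,
                 tolerance = 1e-6)
    expect_equal(superpose(X, sweep(Y %*% t(R), 2, tr, "+"))$rmsd, base,
                 tolerance = 1e-6)
  }
})

test_that("superpose validates its inputs", {
  expect_error(superpose(matrix(0, 3, 3), matrix(0, 4, 3)), "differ")
  s <- superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3))
  expect_false(s$unique)
})

test_that("maximal stack runs are detected, with the length floor applied", {
  p <- circstar_params()
  ss <- extract_nested(base_pairs(c(0, 1, 2), c(9, 8, 7)))
  st <- find_stacks(ss, p)
  expect_length(st, 1L)
  expect_equal(st[[1]]$L, 3L)
  ss2 <- extract_nested(base_pairs(c(0, 1, 4, 5), c(30, 29, 20, 19)))
  st2 <- find_stacks(ss2, p)
  expect_length(st2, 2L)
  expect_true(all(vapply(st2, `[[`, integer(1), "L") == 2L))
  ss3 <- extract_nested(base_pairs(0, 9))
  expect_length(find_stacks(ss3, p), 0L)
  # crossing pairs form stacks of their own
  ss4 <- extract_nested(base_pairs(c(0, 1, 4, 5), c(12, 11, 20, 19)))
  expect_length(find_stacks(ss4, p), 2L)
})

test_that("stacks closing a loop are recovered; short helices drop out", {
  p <- circstar_params()
  ss <- extract_nested(base_pairs(c(0, 1, 2), c(9, 8, 7)))
  stacks <- find_stacks(ss, p)
  lp <- extract_loops(ss, 10L)
  cl <- stacks_closing_loop(lp$loops[[1]], stacks)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$L, 3L)
  # junction: each closing pair sits in its own stack
  jb <- build_junction_structure(junction_spec(c(6, 6, 6), c(3, 3, 3),
                                               c(4, 4), seed = 5))
  ssj <- extract_nested(detect_pairs_geometric(jb$structure))
  lpj <- extract_loops(ssj, jb$structure$n)
  ml <- Filter(function(l) l$kind == "multiloop", lpj$loops)[[1]]
  expect_length(stacks_closing_loop(ml, find_stacks(ssj, p)), 3L)
  # an isolated closing pair below min_stack_len has no stack
  ss1 <- extract_nested(base_pairs(0, 9))
  lp1 <- extract_loops(ss1, 10L)
  expect_length(stacks_closing_loop(lp1$loops[[1]], find_stacks(ss1, p)), 0L)
})

helix_stack_setup <- function(n_bp, seed) {
  h <- build_ideal_helix(n_bp, seed = seed)
  ss <- extract_nested(detect_pairs_geometric(h$structure))
  list(structure = h$structure, stacks = find_stacks(ss, circstar_params()))
}

test_that("a structure matches itself directly at rmsd 0", {
  hx <- helix_stack_setup(6, 11)
  sps <- enumerate_conserved_stack_pairs(hx$stacks, hx$stacks, hx$structure,
                                         hx$structure)
  self_direct <- Filter(function(p)
    p$orientation == "direct" && identical(p$a, p$b), sps)
  expect_gte(length(self_direct), 1L)
  full <- Filter(function(p) p$a$L == 6L, self_direct)
  expect_length(full, 1L)
  expect_lt(full[[1]]$sup$rmsd, 1e-9)
})

test_that("circular permutation of a helix produces a rotated match at rmsd ~0", {
  h <- build_ideal_helix(6, seed = 12)
  perm <- circular_permute(h$structure, 6L, h$truth$intended_pairs)
  ss_a <- extract_nested(h$truth$intended_pairs)
  ss_b <- extract_nested(perm$truth$intended_pairs)
  p <- circstar_params()
  sps <- enumerate_conserved_stack_pairs(find_stacks(ss_a, p),
                                         find_stacks(ss_b, p),
                                         h$structure, perm$structure, p)
  rot_full <- Filter(function(x) x$orientation == "rotated" && x$a$L == 6L,
                     sps)
  expect_gte(length(rot_full), 1L)
  expect_lt(min(vapply(rot_full, function(x) x$sup$rmsd, numeric(1))), 1e-3)
})

test_that("window matches appear exactly when the oracle rmsd admits them", {
  h <- build_ideal_helix(8, seed = 5)
  p8 <- circstar_params(min_stack_len = 8)
  for (angle in c(30, 90)) {
    bent <- bend_helix(h$structure, angle)
    oracle <- quat_rmsd(representative_coords(h$structure),
                        representative_coords(bent))
    ss_a <- extract_nested(h$truth$intended_pairs)
    sps <- enumerate_conserved_stack_pairs(find_stacks(ss_a, p8),
                                           find_stacks(ss_a, p8),
                                           h$structure, bent, p8)
    if (oracle <= p8$rmsd_cutoff) expect_gte(length(sps), 1L)
    else expect_length(sps, 0L)
  }
  # under this geometry a 90 degree hinge is needed to cross the cutoff
  expect_lt(quat_rmsd(representative_coords(h$structure),
                      representative_coords(bend_helix(h$structure, 30))), 4)
  expect_gt(quat_rmsd(representative_coords(h$structure),
                      representative_coords(bend_helix(h$structure, 90))), 4)
})

test_that("rotated-orientation rmsd is symmetric in the structure order", {
  jb <- build_junction_structure(junction_spec(c(6, 5, 7), c(3, 2, 4),
                                               c(4, 5), seed = 7))
  perm <- circular_permute(jb$structure, jb$truth$pivot_options[1],
                           jb$truth$intended_pairs)
  p <- circstar_params()
  a_ss <- extract_nested(jb$truth$intended_pairs)
  b_ss <- extract_nested(perm$truth$intended_pairs)
  closing <- function(ss, n) {
    lp <- extract_loops(ss, n)
    unique(do.call(rbind, lapply(lp$loops, function(l)
      l$closing[, c("i", "j")])))
  }
  ca <- closing(a_ss, jb$structure$n)
  cb <- closing(b_ss, perm$structure$n)
  st_a <- find_stacks(a_ss, p)
  st_b <- find_stacks(b_ss, p)
  ab <- enumerate_conserved_stack_pairs(st_a, st_b, jb$structure,
                                        perm$structure, p, ca, cb)
  ba <- enumerate_conserved_stack_pairs(st_b, st_a, perm$structure,
                                        jb$structure, p, cb, ca)
  key_ab <- sort(vapply(Filter(function(x) x$orientation == "rotated", ab),
                        function(x) {
                          cr <- x$corr[order(x$corr[, 2]), , drop = FALSE]
                          paste(cr[, 2], cr[, 1], collapse = ";")
                        }, character(1)))
  key_ba <- sort(vapply(Filter(function(x) x$orientation == "rotated", ba),
                        function(x) {
                          cr <- x$corr[order(x$corr[, 1]), , drop = FALSE]
                          paste(cr[, 1], cr[, 2], collapse = ";")
                        }, character(1)))
  expect_equal(key_ab, key_ba)
  rms_ab <- vapply(Filter(function(x) x$orientation == "rotated", ab),
                   function(x) x$sup$rmsd, numeric(1))
  rms_ba <- vapply(Filter(function(x) x$orientation == "rotated", ba),
                   function(x) x$sup$rmsd, numeric(1))
  expect_equal(sort(rms_ab), sort(rms_ba), tolerance = 1e-6)
})
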