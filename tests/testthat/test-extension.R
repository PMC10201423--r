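# Abstract interval-topology fixture mirroring a three-stack compatible set:
# in each RNA the six strands cut the circle into six labeled intervals.
# Layout (both structures, length 40):
#   s1_5' [0,3)  a [3,6)   s2_5' [6,9)   b [9,12)  s3_5' [12,15) c [15,18)
#   s3_3' [18,21) d [21,24) s2_3' [24,27) e [27,30) s1_3' [30,33) f [33,40)+seam
fig3_members <- function() {
  list(mk_stack_pair(0, 32, 3, 0, 32, 3, "direct"),
       mk_stack_pair(6, 26, 3, 6, 26, 3, "direct"),
       mk_stack_pair(12, 20, 3, 12, 20, 3, "direct"))
}

test_that("interval labeling produces six corresponding intervals per RNA", {
  lab <- label_intervals(fig3_members(), 40L, 40L)
  expect_length(lab$gaps_a, 6L)
  expect_length(lab$gaps_b, 6L)
  expect_equal(lab$a2b, 1:6)              # identical layouts: identity map
  # a single direct stack pair in two hairpins: 2 intervals per RNA
  one <- list(mk_stack_pair(0, 9, 3, 0, 9, 3, "direct"))
  lab1 <- label_intervals(one, 10L, 10L)
  expect_length(lab1$gaps_a, 2L)
  # empty set: one full-circle interval
  lab0 <- label_intervals(list(), 10L, 12L)
  expect_equal(lab0$gaps_a[[1]]$len, 10L)
  expect_equal(lab0$gaps_b[[1]]$len, 12L)
})

test_that("compatibility follows the interval labels (truth table)", {
  members <- fig3_members()
  # candidate strands in intervals d and f of both RNAs: compatible
  cand_ok <- mk_stack_pair(21, 35, 2, 21, 35, 2, "direct")
  expect_true(is_compatible(cand_ok, members, 40L, 40L))
  # same strands in A, but in B the first strand sits in interval b: not
  cand_bad <- mk_stack_pair(21, 35, 2, 9, 35, 2, "direct")
  expect_false(is_compatible(cand_bad, members, 40L, 40L))
  # crossed (pseudoknotted) placement with matching labels b and d: accepted
  cand_cross <- mk_stack_pair(9, 22, 2, 9, 22, 2, "direct")
  expect_true(is_compatible(cand_cross, members, 40L, 40L))
  # overlap with a member strand is always rejected
  cand_overlap <- mk_stack_pair(2, 35, 2, 21, 35, 2, "direct")
  expect_false(is_compatible(cand_overlap, members, 40L, 40L))
})

test_that("a rotated member exchanges the interval correspondence", {
  # one rotated stack pair: A's enclosed loop region corresponds to the
  # interval of B spanning B's 3'/5' seam
  rot <- list(mk_stack_pair(0, 9, 3, 0, 9, 3, "rotated"))
  lab <- label_intervals(rot, 10L, 10L)
  # A's gap after its 5' strand maps to B's seam-crossing gap
  ga_inner <- which(vapply(lab$gaps_a, function(g) g$start == 3L,
                           logical(1)))
  expect_equal(lab$gaps_b[[lab$a2b[ga_inner]]]$start, 10L %% 10L)
})

test_that("inconsistent cyclic orders are rejected as a labeling error", {
  # three nested stacks in A; in B the inner two exchange places, which is
  # not a rotation of the cyclic strand order
  bad <- list(mk_stack_pair(0, 21, 2, 0, 21, 2, "direct"),
              mk_stack_pair(3, 18, 2, 6, 14, 2, "direct"),
              mk_stack_pair(6, 14, 2, 3, 18, 2, "direct"))
  expect_error(label_intervals(bad, 22L, 22L), "inconsistent")
  # whereas swapping two side-by-side blocks wholesale is a legal rotation
  ok <- list(mk_stack_pair(0, 9, 2, 12, 21, 2, "direct"),
             mk_stack_pair(12, 21, 2, 0, 9, 2, "direct"))
  expect_silent(label_intervals(ok, 22L, 22L))
})

test_that("combined rmsd equals the single-pair rmsd for singleton sets", {
  jb <- build_junction_structure(junction_spec(c(6, 5, 7), c(3, 2, 4),
                                               c(4, 5), seed = 7))
  pivot <- jb$truth$pivot_options[1]
  perm <- circular_permute(jb$structure, pivot, jb$truth$intended_pairs)
  p <- circstar_params()
  a_ss <- extract_nested(jb$truth$intended_pairs)
  b_ss <- extract_nested(perm$truth$intended_pairs)
  closing <- function(ss, n) {
    lp <- extract_loops(ss, n)
    unique(do.call(rbind, lapply(lp$loops, function(l)
      l$closing[, c("i", "j")])))
  }
  st_a <- find_stacks(a_ss, p)
  st_b <- find_stacks(b_ss, p)
  sps <- enumerate_conserved_stack_pairs(st_a, st_b, jb$structure,
                                         perm$structure, p,
                                         closing(a_ss, jb$structure$n),
                                         closing(b_ss, perm$structure$n))
  sp <- sps[[1]]
  expect_equal(combined_rmsd(list(sp), jb$structure, perm$structure),
               sp$sup$rmsd, tolerance = 1e-9)
  # identical structures, full direct self-set: rmsd 0
  self <- enumerate_conserved_stack_pairs(st_a, st_a, jb$structure,
                                          jb$structure, p,
                                          closing(a_ss, jb$structure$n),
                                          closing(a_ss, jb$structure$n))
  self_full <- Filter(function(x)
    x$orientation == "direct" && identical(x$a, x$b) &&
      x$a$L == max(vapply(st_a, `[[`, integer(1), "L")), self)
  expect_lt(combined_rmsd(self_full, jb$structure, jb$structure), 1e-9)
  # two ground-truth pairs from the noise-free permuted fixture: < 1e-3
  n <- jb$structure$n
  truthful <- Filter(function(x)
    all(x$corr[, 2] == (x$corr[, 1] - pivot) %% n), sps)
  two <- NULL
  for (r in truthful) for (s in truthful) {
    if (identical(s$key, r$key)) next
    if (is_compatible(s, list(r), n, perm$structure$n)) {
      two <- list(r, s); break
    }
  }
  expect_false(is.null(two))
  expect_lt(combined_rmsd(two, jb$structure, perm$structure), 1e-3)
})

test_that("seed extension matches brute-force pinned enumeration", {
  # small randomized instances; geometry is noise-free so the RMSD cutoff
  # never binds and the search is a pure clique/adjacency problem
  for (seed in c(3, 8, 15)) {
    jb <- build_junction_structure(random_junction_spec(seed))
    perm <- circular_permute(jb$structure, jb$truth$pivot_options[1],
                             jb$truth$intended_pairs)
    p <- circstar_params()
    a_ss <- extract_nested(jb$truth$intended_pairs)
    b_ss <- extract_nested(perm$truth$intended_pairs)
    a_lp <- extract_loops(a_ss, jb$structure$n)
    b_lp <- extract_loops(b_ss, perm$structure$n)
    closing <- function(lp) unique(do.call(rbind, lapply(lp$loops,
      function(l) l$closing[, c("i", "j")])))
    sps <- circstar:::.prune_subwindow_pairs(
      enumerate_conserved_stack_pairs(
        find_stacks(a_ss, p), find_stacks(b_ss, p), jb$structure,
        perm$structure, p, closing(a_lp), closing(b_lp)))
    rot <- Filter(function(x) x$orientation == "rotated", sps)
    expect_gte(length(rot), 1L)
    pinned <- rot[1]
    pool <- Filter(function(x) !identical(x$key, pinned[[1]]$key), sps)
    pool <- pool[seq_len(min(9, length(pool)))]
    seed_obj <- list(closing_matches = pinned)
    got <- extend_seed(seed_obj, c(pinned, pool), jb$structure,
                       perm$structure, p)
    got_keys <- unique(lapply(got, function(s)
      sort(vapply(s$members, `[[`, character(1), "key"))))
    want_keys <- brute_maximal_sets(pinned, pool, jb$structure,
                                    perm$structure, p)
    expect_setequal(lapply(got_keys, paste, collapse = "|"),
                    lapply(want_keys, paste, collapse = "|"))
    # pinned pairs are present in every reported set
    for (s in got)
      expect_true(pinned[[1]]$key %in%
                    vapply(s$members, `[[`, character(1), "key"))
    # reported rmsd always within the cutoff
    for (s in got) expect_lte(s$rmsd, p$rmsd_cutoff)
  }
})

test_that("a seed with no candidates returns exactly itself", {
  su_jb <- build_junction_structure(junction_spec(c(6, 5, 7), c(3, 2, 4),
                                                  c(4, 5), seed = 7))
  perm <- circular_permute(su_jb$structure, su_jb$truth$pivot_options[1],
                           su_jb$truth$intended_pairs)
  p <- circstar_params()
  a_ss <- extract_nested(su_jb$truth$intended_pairs)
  b_ss <- extract_nested(perm$truth$intended_pairs)
  closing <- function(ss, n) {
    lp <- extract_loops(ss, n)
    unique(do.call(rbind, lapply(lp$loops, function(l)
      l$closing[, c("i", "j")])))
  }
  sps <- enumerate_conserved_stack_pairs(
    find_stacks(a_ss, p), find_stacks(b_ss, p),
    su_jb$structure, perm$structure, p,
    closing(a_ss, su_jb$structure$n), closing(b_ss, perm$structure$n))
  rot <- Filter(function(x) x$orientation == "rotated", sps)[[1]]
  res <- extend_seed(list(closing_matches = list(rot)), list(rot),
                     su_jb$structure, perm$structure, p)
  expect_length(res, 1L)
  expect_length(res[[1]]$members, 1L)
  expect_equal(res[[1]]$members[[1]]$key, rot$key)
})

test_that("candidates beyond the adjacency distance are excluded", {
  # two far-apart hairpin stacks in both structures; with ext_dist 15 the
  # distal pair (gap 20 nt) is unreachable from the pinned proximal pair
  mk_two_hairpin <- function() {
    prs <- base_pairs(c(0, 1, 2, 29, 30, 31), c(9, 8, 7, 38, 37, 36))
    set.seed(1)
    n <- 45L
    # lay C1' atoms on a gentle spiral so superpositions are well defined
    t <- (0:(n - 1)) * 0.4
    at <- data.frame(seq = 0:(n - 1), atom = "C1'",
                     x = 6 * cos(t), y = 6 * sin(t), z = (0:(n - 1)) * 1.5)
    st <- circstar:::new_rna_structure("twohp", rep("A", n), 1:n,
                                       rep("", n), at)
    list(st = st, prs = prs)
  }
  fx <- mk_two_hairpin()
  p <- circstar_params()
  stacks <- find_stacks(extract_nested(fx$prs), p)
  expect_length(stacks, 2L)
  sps <- enumerate_conserved_stack_pairs(stacks, stacks, fx$st, fx$st, p)
  near <- Filter(function(x) x$orientation == "direct" &&
                   identical(x$a, x$b) && x$a$i == 0L && x$a$L == 3L, sps)
  far <- Filter(function(x) x$orientation == "direct" &&
                  identical(x$a, x$b) && x$a$i == 29L && x$a$L == 3L, sps)
  expect_length(near, 1L); expect_length(far, 1L)
  res <- extend_seed(list(closing_matches = near), c(near, far),
                     fx$st, fx$st, p)
  for (s in res)
    expect_false(far[[1]]$key %in%
                   vapply(s$members, `[[`, character(1), "key"))
  # raising ext_dist above the 20-nt gap makes it reachable
  p2 <- circstar_params(ext_dist = 25)
  res2 <- extend_seed(list(closing_matches = near), c(near, far),
                      fx$st, fx$st, p2)
  expect_true(any(vapply(res2, function(s)
    far[[1]]$key %in% vapply(s$members, `[[`, character(1), "key"),
    logical(1))))
})
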