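test_that("packaged binding sites match the published residue counts", {
  expect_equal(nrow(binding_sites("TASK-1")), 15)
  expect_equal(nrow(binding_sites("NaV1.5")), 4)
  expect_equal(nrow(binding_sites("KV1.5", "CC")), 16)
  expect_equal(nrow(binding_sites("KV1.5", "SP")), 12)
  expect_error(binding_sites("KV11.1"), "no such")
})

test_that("min-max pose scoring matches hand-enumerated values", {
  two <- data.frame(compound = c("A", "B"), pose_id = c("p1", "p2"),
                    dg_bind = c(-50, -40), n_contacts = c(10, 5))
  s <- score_poses(two)
  expect_equal(s$dgbind_norm, c(1, 0))
  expect_equal(s$int_norm, c(1, 0))
  expect_equal(s$normt, c(1, 0))
  three <- data.frame(compound = c("A", "B", "C"),
                      pose_id = c("p1", "p2", "p3"),
                      dg_bind = c(-50, -45, -40), n_contacts = c(5, 8, 8))
  s3 <- score_poses(three)
  expect_equal(s3$dgbind_norm, c(1, 0.5, 0))
  expect_equal(s3$int_norm, c(0, 1, 1))
  expect_equal(s3$normt, c(0.5, 0.75, 0.5))
  # contacts first, then normt: p2, p3, p1
  expect_equal(rank_and_select(s3)$ordering, c("B", "C", "A"))
  # degenerate pose set normalizes to all ones
  same <- data.frame(compound = "A", pose_id = c("p1", "p2"),
                     dg_bind = c(-30, -30), n_contacts = c(4, 4))
  expect_true(all(score_poses(same)$normt == 1))
})

test_that("scoring is invariant to affine rescaling of the energy column", {
  set.seed(3)
  poses <- data.frame(compound = letters[1:6], pose_id = paste0("p", 1:6),
                      dg_bind = runif(6, -60, -30),
                      n_contacts = sample(0:12, 6))
  a <- score_poses(poses)
  poses2 <- poses
  poses2$dg_bind <- 3.7 * poses2$dg_bind - 11
  b <- score_poses(poses2)
  expect_equal(a$dgbind_norm, b$dgbind_norm, tolerance = 1e-12)
  expect_equal(a$normt, b$normt, tolerance = 1e-12)
})

test_that("duplicating poses leaves the compound ordering unchanged", {
  set.seed(4)
  poses <- data.frame(compound = rep(c("A", "B", "C"), each = 2),
                      pose_id = paste0("p", 1:6),
                      dg_bind = runif(6, -55, -35), n_contacts = sample(0:9, 6))
  ord1 <- rank_and_select(score_poses(poses))$ordering
  dup <- rbind(poses, transform(poses, pose_id = paste0(pose_id, "_dup")))
  ord2 <- rank_and_select(score_poses(dup))$ordering
  expect_equal(ord1, ord2)
})

test_that("channel RANK follows the best-of-sites rule and re-densifies", {
  expect_equal(rank_channel(list(c("B", "A", "C"))),
               c(A = 2L, B = 1L, C = 3L))
  # A is 1st on one site, 20th-ish on the other: min rule keeps it first
  two_sites <- list(c("A", "B", "C"), c("C", "B", "A"))
  r <- rank_channel(two_sites)
  expect_equal(r[["A"]], 1L)
  expect_equal(sort(unname(r)), 1:3)
})

test_that("channel RANK equals a brute-force enumeration oracle", {
  # oracle: independent re-derivation by explicit position tables
  oracle <- function(ords) {
    cmp <- sort(unique(unlist(ords)))
    best <- sapply(cmp, function(cc) {
      min(sapply(ords, function(o) {
        p <- which(o == cc)
        if (length(p) == 0) length(o) + 1 else p
      }))
    })
    r <- integer(length(cmp))
    r[order(best, cmp)] <- seq_along(cmp)
    names(r) <- cmp
    r
  }
  set.seed(9)
  cmps <- c("A", "B", "C")
  for (k in 1:20) {
    o1 <- sample(cmps)
    o2 <- sample(cmps, sample(2:3, 1))   # second site may miss a compound
    ords <- list(o1, o2)
    expect_equal(rank_channel(ords), oracle(ords))
  }
})

test_that("GLOBAL RANK sums channel ranks and matches exhaustive ordering", {
  cr <- list(ch1 = c(A = 1L, B = 2L), ch2 = c(A = 2L, B = 1L),
             ch3 = c(A = 1L, B = 2L))
  g <- rank_global(cr)
  expect_equal(g$compound, c("A", "B"))
  expect_equal(g$global_rank, c(4, 5))
  # single channel: global order equals that channel's order
  one <- rank_global(list(ch = c(A = 2L, B = 1L, C = 3L)))
  expect_equal(one$compound, c("B", "A", "C"))
  # 5-compound, 3-channel fixture vs brute-force oracle
  set.seed(12)
  cmps <- sprintf("C%02d", 1:5)
  ranks <- lapply(1:3, function(i) {
    r <- sample(5); names(r) <- cmps; r
  })
  names(ranks) <- paste0("ch", 1:3)
  g5 <- rank_global(ranks)
  m <- sapply(ranks, function(r) r[cmps])
  tot <- rowSums(m)
  o <- order(tot, apply(m, 1, min), cmps)
  expect_equal(g5$compound, cmps[o])
  expect_equal(g5$global_rank, unname(tot[o]))
  expect_error(rank_global(list(a = c(A = 1L), b = c(B = 1L))),
               "inconsistent")
})

test_that("contact counting respects the 5 A cutoff on a minimal structure", {
  skip_if_not_installed("bio3d")
  dir <- withr::local_tempdir()
  site <- data.frame(chain = "A", resno = 1:2, aa = c("A", "A"))
  rec <- data.frame(chain = "A", resno = 1:2, x = c(0, 100), y = 0, z = 0)
  for (dz in c(4.9, 5.1)) {
    lig <- data.frame(x = 0, y = 0, z = dz)
    f <- file.path(dir, sprintf("pose_%s.pdb", dz))
    afsilico:::.write_pose_pdb(f, rec, lig)
    expect_equal(count_contacts(f, site), as.integer(dz < 5))
  }
  # TASK-1 site has 15 residues, so any count is bounded by 15
  task1 <- binding_sites("TASK-1")
  expect_lte(nrow(task1), 15)
})

test_that("contact counting is invariant under a rigid-body transformation", {
  skip_if_not_installed("bio3d")
  dir <- withr::local_tempdir()
  site <- data.frame(chain = "A", resno = 1:3)
  rec <- data.frame(chain = "A", resno = 1:3,
                    x = c(0, 30, 60), y = 0, z = 0)
  lig <- data.frame(x = c(3, 33), y = 0, z = 0)   # contacts residues 1, 2
  f1 <- file.path(dir, "orig.pdb")
  afsilico:::.write_pose_pdb(f1, rec, lig)
  # rotate 90 deg about z and translate both molecules jointly
  rot <- function(d) data.frame(chain = d$chain, resno = d$resno,
                                x = -d$y + 5, y = d$x - 2, z = d$z + 7)
  rec2 <- rot(cbind(rec)); lig2 <- rot(cbind(lig, chain = NA, resno = NA))
  f2 <- file.path(dir, "moved.pdb")
  afsilico:::.write_pose_pdb(f2, rec2, lig2[c("x", "y", "z")])
  expect_equal(count_contacts(f1, site), 2L)
  expect_equal(count_contacts(f2, site), 2L)
})

test_that("a strictly dominant compound ranks first globally", {
  poses <- gen_pose_set(n_compounds = 5, n_poses = 3, winner = "C03",
                        seed = 21)
  out <- rank_compounds(poses)
  expect_equal(out$global$compound[1], "C03")
  expect_equal(out$global$position, 1:5)
  for (r in out$channel_ranks) expect_equal(sort(unname(r)), 1:5)
})
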