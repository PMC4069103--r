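# build a donor(N)-H...acceptor(O) triad with a given donor-acceptor
# distance and donor-H-acceptor angle (H 1.0 A from the donor)
triad <- function(da_dist, dha_angle) {
  ang <- (180 - dha_angle) * pi / 180
  cc <- cos(ang)
  r <- -cc + sqrt(cc^2 + (da_dist^2 - 1))
  rbind(
    c(0, 0, 0), # donor
    c(1, 0, 0), # hydrogen
    c(1 + r * cc, r * sin(ang), 0) # acceptor
  )
}

triad_top <- tibble::tibble(
  chain = "X", resno = c(1L, 1L, 2L), resname = c("DON", "DON", "ACC"),
  atom = c("N", "H", "O"), element = c("N", "H", "O")
)

test_that("the distance and angle criteria gate acceptance (inclusive bounds)", {
  crit <- hbond_criteria()
  accept <- function(dist, ang) {
    nrow(detect_hbonds(triad(dist, ang), triad_top, crit)) > 0
  }
  expect_true(accept(2.9, 165)) # comfortably inside
  expect_false(accept(3.6, 170)) # distance out
  expect_false(accept(3.0, 130)) # angle out
  expect_true(accept(3.5, 145)) # both exactly at the boundary
  expect_false(accept(3.51, 165))

  hb <- detect_hbonds(triad(2.9, 165), triad_top, crit)
  expect_equal(hb$distance, 2.9, tolerance = 1e-8)
  expect_equal(hb$angle, 165, tolerance = 1e-6)
})

test_that("detection is invariant under rigid motion of the frame", {
  set.seed(3)
  fr <- triad(3.1, 160)
  base <- detect_hbonds(fr, triad_top)
  for (k in 1:3) {
    moved <- rigid_move(fr, random_rotation(), rnorm(3, sd = 20))
    got <- detect_hbonds(moved, triad_top)
    expect_equal(nrow(got), nrow(base))
    expect_equal(got$distance, base$distance, tolerance = 1e-8)
    expect_equal(got$angle, base$angle, tolerance = 1e-6)
  }
})

test_that("tightening the criteria never adds bonds", {
  set.seed(13)
  # a soup of waters: every O has two attached hydrogens
  n_w <- 12
  centers <- matrix(runif(n_w * 3, 0, 8), n_w, 3)
  coords <- NULL
  top <- NULL
  for (w in seq_len(n_w)) {
    o <- centers[w, ]
    coords <- rbind(coords, o, o + c(0.95, 0, 0), o + c(-0.3, 0.9, 0))
    top <- rbind(top, tibble::tibble(
      chain = "W", resno = as.integer(w), resname = "HOH",
      atom = c("O", "H1", "H2"), element = c("O", "H", "H")
    ))
  }
  loose <- detect_hbonds(coords, top, hbond_criteria(3.5, c(145, 180)))
  tight <- detect_hbonds(coords, top, hbond_criteria(3.0, c(155, 180)))
  key <- function(d) {
    if (nrow(d) == 0) character(0) else {
      paste(d$donor_resno, d$hydrogen, d$acceptor_resno)
    }
  }
  expect_true(all(key(tight) %in% key(loose)))
  expect_lte(nrow(tight), nrow(loose))

  # loose set equals a brute-force all-triples enumeration
  brute <- NULL
  hs <- which(top$element == "H")
  os <- which(top$element == "O")
  for (h in hs) {
    dd <- sqrt(colSums((t(coords[os, ]) - coords[h, ])^2))
    d <- os[which.min(dd)]
    if (min(dd) > 1.25) next
    for (a in setdiff(os, d)) {
      da <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      v1 <- coords[d, ] - coords[h, ]
      v2 <- coords[a, ] - coords[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (da <= 3.5 && ang >= 145) {
        brute <- c(brute, paste(top$resno[d], top$atom[h], top$resno[a]))
      }
    }
  }
  expect_setequal(key(loose), brute)
})

test_that("heavy-atom fallback screens unprotonated structures", {
  top_noh <- triad_top[c(1, 3), ]
  fr <- triad(3.0, 165)[c(1, 3), ]
  expect_error(detect_hbonds(fr, top_noh), "heavy")
  hb <- detect_hbonds(fr, top_noh, mode = "heavy")
  expect_equal(nrow(hb), 2) # both directions at distance-only screening
  expect_true(all(is.na(hb$angle)))
  expect_true(isTRUE(attr(hb, "heavy_atom_mode")))
})

test_that("persistence is the mean per-frame bond indicator", {
  crit <- hbond_criteria()
  on <- triad(2.9, 165)
  off <- triad(4.5, 165)

  all_on <- trajectory(triad_top, replicate(6, on, simplify = FALSE))
  expect_equal(
    hbond_persistence(all_on, list(chain = "X", resno = 1), list(chain = "X", resno = 2)),
    1.0
  )
  alternating <- trajectory(triad_top, rep(list(on, off), 4))
  expect_equal(
    hbond_persistence(alternating, list(chain = "X", resno = 1), list(chain = "X", resno = 2)),
    0.5
  )
  nine_of_ten <- trajectory(triad_top, c(replicate(9, on, simplify = FALSE), list(off)))
  expect_equal(
    hbond_persistence(nine_of_ten, list(chain = "X", resno = 1), list(chain = "X", resno = 2)),
    0.9
  )
  expect_error(
    hbond_persistence(all_on, list(chain = "Z", resno = 9), list(chain = "X", resno = 2)),
    "absent"
  )
})

test_that("a bridging water donating twice and accepting once has degree 3", {
  # water at the origin: donates to acceptors on residues 20 and 65,
  # accepts from the carboxyl donor on residue 484
  coords <- rbind(
    c(0, 0, 0), # Wat O
    c(0.95, 0, 0), # Wat H1
    c(0, 0.95, 0), # Wat H2
    c(2.8, 0, 0), # acceptor O, res 20
    c(0, 2.8, 0), # acceptor O, res 65
    c(0, 0, 3.0), # donor OD2, res 484
    c(0, 0, 1.0) # donor H, res 484
  )
  top <- tibble::tibble(
    chain = c("W", "W", "W", "B", "B", "B", "B"),
    resno = c(2436L, 2436L, 2436L, 20L, 65L, 484L, 484L),
    resname = c("HOH", "HOH", "HOH", "ASN", "TRP", "ASP", "ASP"),
    atom = c("O", "H1", "H2", "OD1", "O", "OD2", "HD2"),
    element = c("O", "H", "H", "O", "O", "O", "H")
  )
  net <- extract_network(coords, top,
    seed_residues = tibble::tibble(chain = "B", resno = 484)
  )
  expect_equal(nrow(net$edges), 3)
  water_touch <- sum(net$edges$donor_resno == 2436 | net$edges$acceptor_resno == 2436)
  expect_equal(water_touch, 3)

  # an isolated seed yields a single node and no edges
  lone <- extract_network(coords[6:7, , drop = FALSE], top[6:7, ],
    seed_residues = tibble::tibble(chain = "B", resno = 484)
  )
  expect_equal(nrow(lone$edges), 0)
  expect_equal(nrow(lone$nodes), 1)
})

test_that("network differences report shared, lost and gained residue pairs", {
  coords <- triad(2.9, 165)
  net_a <- extract_network(coords, triad_top,
    seed_residues = tibble::tibble(chain = "X", resno = 1)
  )
  expect_equal(diff_networks(net_a, net_a)$lost, character(0))
  expect_equal(diff_networks(net_a, net_a)$gained, character(0))

  net_b <- net_a
  net_b$edges <- net_b$edges[0, ]
  d <- diff_networks(net_a, net_b)
  expect_length(d$lost, 1)
  expect_length(d$shared, 0)
  d2 <- diff_networks(net_b, net_a)
  expect_length(d2$gained, 1)
})
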