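# An engineered A/U pair: U rotated and translated so its O4 sits exactly
# d Angstrom from A's N6 along the N6 exocyclic direction, O4 pointing back.
engineered_pair <- function(d) {
  tplA <- base_template("A")
  tplU <- base_template("U")
  n6 <- tplA["N6", 1:2]
  u <- n6 / sqrt(sum(n6^2))       # template is centred at the centroid
  target <- n6 + d * u
  o4 <- tplU["O4", 1:2]
  # rotate U so its centroid-to-O4 axis is -u, then put O4 on the target
  q <- o4 / sqrt(sum(o4^2))
  v <- -u
  cs <- sum(q * v); sn <- q[1] * v[2] - q[2] * v[1]
  R <- matrix(c(cs, sn, -sn, cs), 2, 2)
  xyU <- sweep(tplU[, 1:2] %*% t(R), 2, target - as.vector(R %*% o4), `+`)
  make_structure(list(
    list(chain = "A", res = 1, code = "A",
         atoms = data.frame(name = rownames(tplA),
                            element = attr(tplA, "element"),
                            x = tplA[, 1], y = tplA[, 2], z = 0)),
    list(chain = "A", res = 2, code = "U",
         atoms = data.frame(name = rownames(tplU),
                            element = attr(tplU, "element"),
                            x = xyU[, 1], y = xyU[, 2], z = 0))))
}

test_that("default criteria are the classical heavy-atom cutoffs", {
  p <- default_params()
  expect_equal(p$max_da_distance, 3.9)
  expect_equal(p$min_ada_angle, 90)
  expect_equal(p$min_daa_angle, 90)
  expect_error(hbond_params(max_da_distance = -1))
  expect_error(hbond_params(min_daa_angle = 200))
})

test_that("an engineered N6->O4 contact at 2.9 A gives exactly that bond", {
  hb <- detect_hbonds(engineered_pair(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "N6")
  expect_equal(hb$acceptor_atom, "O4")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gte(hb$angle_at_donor, 90)
  expect_gte(hb$angle_at_acceptor, 90)
})

test_that("pairs beyond the distance cutoff yield no bonds", {
  expect_equal(nrow(detect_hbonds(engineered_pair(5.0))), 0)
  # 2.9 A contact disappears when the cutoff is tightened below it
  p <- hbond_params(max_da_distance = 2.5)
  expect_equal(nrow(detect_hbonds(engineered_pair(2.9), params = p)), 0)
})

test_that("every emitted bond satisfies all three criteria", {
  set.seed(21)
  for (rep in 1:5) {
    spec <- sample_fixture_spec(seed = 100 + rep)
    s <- parse_structure(paste(generate_fixture(spec), collapse = "\n"))
    hb <- detect_hbonds(s)
    p <- default_params()
    expect_true(all(hb$distance <= p$max_da_distance))
    expect_true(all(hb$angle_at_donor >= p$min_ada_angle))
    expect_true(all(hb$angle_at_acceptor >= p$min_daa_angle))
    lib <- base_library()
    expect_true(all(mapply(function(b, a) a %in% lib[[b]]$donors,
                           hb$donor_base, hb$donor_atom)))
    expect_true(all(mapply(function(b, a) a %in% lib[[b]]$acceptors,
                           hb$acceptor_base, hb$acceptor_atom)))
  }
})

test_that("output is invariant under atom-record permutation", {
  set.seed(31)
  spec <- sample_fixture_spec(sizes = 4, seed = 7)
  lines <- generate_fixture(spec)
  atoms <- lines[lines != "END"]
  shuffled <- c(sample(atoms), "END")
  a <- detect_hbonds(parse_structure(paste(lines, collapse = "\n")))
  b <- detect_hbonds(parse_structure(paste(shuffled, collapse = "\n")))
  key <- function(h) paste(h$donor_res, h$donor_atom,
                           h$acceptor_res, h$acceptor_atom)
  expect_setequal(key(a), key(b))
})

test_that("detection equals a naive all-pairs scan (prefilter is exact)", {
  naive <- function(structure, library = base_library(),
                    params = default_params()) {
    out <- list()
    n <- length(structure$bases)
    for (di in seq_len(n)) for (ai in seq_len(n)) {
      if (di == ai) next
      db <- structure$bases[[di]]; ab <- structure$bases[[ai]]
      dl <- library[[db$base_code]]; al <- library[[ab$base_code]]
      for (datom in intersect(dl$donors, db$atoms$name)) {
        for (aatom in intersect(al$acceptors, ab$atoms$name)) {
          dp <- unlist(db$atoms[db$atoms$name == datom, c("x", "y", "z")])
          ap <- unlist(ab$atoms[ab$atoms$name == aatom, c("x", "y", "z")])
          d <- sqrt(sum((dp - ap)^2))
          if (d > params$max_da_distance) next
          dant <- unlist(db$atoms[db$atoms$name == dl$antecedent[[datom]],
                                  c("x", "y", "z")])
          aant <- unlist(ab$atoms[ab$atoms$name == al$antecedent[[aatom]],
                                  c("x", "y", "z")])
          ang <- function(a, b, c) {
            u <- a - b; v <- c - b
            acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) *
              180 / pi
          }
          if (ang(dant, dp, ap) < params$min_ada_angle) next
          if (ang(dp, ap, aant) < params$min_daa_angle) next
          out[[length(out) + 1L]] <- paste(di, datom, ai, aatom)
        }
      }
    }
    sort(unlist(out))
  }
  set.seed(41)
  for (rep in 1:3) {
    spec <- sample_fixture_spec(seed = 200 + rep)
    s <- parse_structure(paste(generate_fixture(spec), collapse = "\n"))
    hb <- detect_hbonds(s)
    got <- sort(paste(hb$donor_index, hb$donor_atom,
                      hb$acceptor_index, hb$acceptor_atom))
    expect_identical(got, naive(s))
  }
})

test_that("narrowing the distance cutoff never adds bonds", {
  set.seed(51)
  spec <- sample_fixture_spec(seed = 9)
  s <- parse_structure(paste(generate_fixture(spec), collapse = "\n"))
  key <- function(h) paste(h$donor_index, h$donor_atom,
                           h$acceptor_index, h$acceptor_atom)
  prev <- key(detect_hbonds(s, params = hbond_params(max_da_distance = 4.5)))
  for (cut in c(3.9, 3.4, 3.0, 2.5)) {
    cur <- key(detect_hbonds(s, params = hbond_params(max_da_distance = cut)))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("a missing antecedent atom skips the bond with a warning", {
  s <- engineered_pair(2.9)
  # remove C4, the antecedent of the acceptor O4
  at <- s$bases[[2]]$atoms
  s$bases[[2]]$atoms <- at[at$name != "C4", ]
  expect_warning(hb <- detect_hbonds(s), "antecedent")
  expect_equal(nrow(hb), 0)
})

test_that("a residue outside the library is a named error", {
  s <- engineered_pair(2.9)
  s$bases[[2]]$base_code <- "XXX"
  expect_error(detect_hbonds(s), "XXX")
})

test_that("criteria round-trip through a YAML config file", {
  p <- hbond_params(max_da_distance = 3.4, min_ada_angle = 100,
                    min_daa_angle = 95)
  f <- tempfile(fileext = ".yaml")
  save_config(p, f)
  expect_equal(load_config(f)$params, p)
})
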