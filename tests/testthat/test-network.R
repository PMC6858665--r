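# small expression fixture with planted correlated blocks
planted_expr <- function(n_mod = 2, size = 10, n_bg = 20, n_samp = 30,
                         rho = 0.9, sd_sig = 2.5) {
  n <- n_mod * size + n_bg
  x <- matrix(rnorm(n * n_samp, 5, 0.3), n, n_samp)
  lat <- matrix(rnorm(n_mod * n_samp), n_mod, n_samp)
  for (m in seq_len(n_mod)) {
    rows <- ((m - 1) * size + 1):(m * size)
    for (i in rows) {
      x[i, ] <- 5 + sd_sig * (sqrt(rho) * lat[m, ] +
                                sqrt(1 - rho) * rnorm(n_samp))
    }
  }
  rownames(x) <- paste0("t", seq_len(n))
  colnames(x) <- paste0("s", seq_len(n_samp))
  list(x = x, latents = lat,
       truth = rep(c(paste0("mod", seq_len(n_mod)), "none"),
                   c(rep(size, n_mod), n_bg)))
}

test_that("the VST transform stabilizes and flags zero variance", {
  m <- matrix(c(0, 7, 7, 7, 0, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  v <- vst_transform(m, factors = setNames(rep(1, 3), paste0("s", 1:3)))
  expect_equal(unname(v["a", ]), c(0, 3, 3))
  # doubling a sample's counts and its factor leaves the column unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  v2 <- vst_transform(m2, factors = setNames(c(1, 2, 1), paste0("s", 1:3)))
  expect_equal(v2, v, ignore_attr = TRUE)
  mzv <- rbind(m, c = c(5, 5, 5))
  vz <- vst_transform(mzv, factors = setNames(rep(1, 3), paste0("s", 1:3)))
  expect_equal(attr(vz, "zero_variance"), "c")
})

test_that("soft adjacency raises |r| to the power beta", {
  x <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1,
                -1, 1, 1, -1), 4, 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  a <- soft_adjacency(x, beta = 12)
  expect_equal(a["t1", "t2"], 1)       # perfectly correlated
  expect_equal(a["t1", "t3"], 1)       # |r| = 1 (anti), unsigned
  expect_equal(a["t1", "t4"], 0)       # r = 0
  expect_equal(diag(a), rep(1, 4), ignore_attr = TRUE)
  # numeric value: r = 0.9 -> 0.9^12
  y <- rbind(u = c(0.9, 1.9, 3.1, 3.9, 5.2),
             v = c(1, 2, 3, 4, 5))
  r <- cor(y["u", ], y["v", ])
  expect_equal(soft_adjacency(y, 12)["u", "v"], abs(r)^12)
  expect_equal(abs(0.9)^12, 0.28242954, tolerance = 1e-6)
  expect_error(soft_adjacency(x, beta = 0.5), "beta")
})

test_that("TOM similarity matches hand values and the triple loop", {
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.4) # collapses to adjacency
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  # (0.25 + 0.5) / (min(1,1) + 1 - 0.5)
  expect_equal(tom_similarity(a3)[1, 2], 0.5)
  withr::with_seed(81, {
    for (rep in 1:5) {
      n <- sample(10:30, 1)
      r <- matrix(runif(n * n), n, n)
      a <- (r + t(r)) / 2
      diag(a) <- 1
      expect_equal(tom_similarity(a), bf_tom(a), ignore_attr = TRUE)
    }
  })
})

test_that("module detection recovers planted blocks and stays silent on
          noise", {
  withr::with_seed(82, {
    pe <- planted_expr()
    tom <- tom_similarity(soft_adjacency(pe$x, 12))
    mods <- detect_modules(tom, network_config(min_module_size = 5))
    expect_equal(length(setdiff(unique(mods), "grey")), 2L)
    # block members share one label; background is grey
    expect_equal(length(unique(mods[1:10])), 1L)
    expect_equal(length(unique(mods[11:20])), 1L)
    expect_true(all(mods[21:40] == "grey"))
    # labels ordered by size are invariant to input order
    perm <- sample(nrow(pe$x))
    tom_p <- tom_similarity(soft_adjacency(pe$x[perm, ], 12))
    mods_p <- detect_modules(tom_p, network_config(min_module_size = 5))
    expect_equal(mods_p[rownames(pe$x)], mods[rownames(pe$x)])

    # pure noise: everything grey
    noise <- matrix(rnorm(50 * 30), 50, 30,
                    dimnames = list(paste0("n", 1:50), paste0("s", 1:30)))
    tn <- tom_similarity(soft_adjacency(noise, 12))
    expect_warning(mn <- detect_modules(tn, network_config()), "grey")
    expect_true(all(mn == "grey"))
  })
})

test_that("eigengenes track the planted latent factor", {
  withr::with_seed(83, {
    pe <- planted_expr(n_mod = 1, size = 15, n_bg = 0)
    mods <- setNames(rep("M1", 15), rownames(pe$x))
    eg <- module_eigengenes(pe$x, mods)
    expect_gte(abs(cor(eg["M1", ], pe$latents[1, ])), 0.95)
    # eigengene correlates positively with the member mean profile
    expect_gte(cor(eg["M1", ], colMeans(t(scale(t(pe$x))))), 0)

    # singleton module: the standardized profile itself
    one <- pe$x[1, , drop = FALSE]
    eg1 <- module_eigengenes(one, setNames("M1", rownames(one)))
    expect_equal(unname(eg1["M1", ]), as.numeric(scale(one[1, ])))
    # duplicated transcript: eigengene correlates 1 with each copy
    two <- rbind(a = pe$x[1, ], b = pe$x[1, ])
    eg2 <- module_eigengenes(two, setNames(c("M1", "M1"), c("a", "b")))
    expect_equal(abs(cor(eg2["M1", ], two["a", ])), 1)
  })
})

test_that("module-trait correlation flags the driving trait", {
  withr::with_seed(84, {
    n <- 24
    trait <- rep(c(1, 0, 0), each = 8)
    traits <- cbind(heat_V3 = trait, cold_V3 = rep(c(0, 1, 0), each = 8))
    eg <- rbind(M1 = trait, M2 = rnorm(n))
    mt <- module_trait_correlation(eg, traits)
    m1h <- dplyr::filter(mt, profile == "M1", trait == "heat_V3")
    expect_equal(m1h$r, 1)
    expect_lt(m1h$p_value, 1e-12)
    m2 <- dplyr::filter(mt, profile == "M2")
    expect_true(all(abs(m2$r) < 0.5))
    # constant trait reported as absent
    traits2 <- cbind(traits, flat = rep(1, n))
    mt2 <- module_trait_correlation(eg, traits2)
    expect_true(all(is.na(
      dplyr::filter(mt2, trait == "flat")$r)))
  })
})

test_that("kME and kIM follow their definitions", {
  withr::with_seed(85, {
    pe <- planted_expr(n_mod = 2, size = 6, n_bg = 4)
    adj <- soft_adjacency(pe$x, 6)
    mods <- setNames(c(rep("M1", 6), rep("M2", 6), rep("grey", 4)),
                     rownames(pe$x))
    eg <- module_eigengenes(pe$x, mods)
    kk <- kme_kim(pe$x, adj, mods, eg)
    # transcript identical to the eigengene profile has kME 1
    x2 <- rbind(pe$x, probe = eg["M1", ])
    mods2 <- c(mods, probe = "M1")
    adj2 <- soft_adjacency(x2, 6)
    kk2 <- kme_kim(x2, adj2, mods2, module_eigengenes(x2, mods2))
    expect_gte(kk2$kme["probe", "M1"], 0.999)
    # kIM equals the module-restricted adjacency row sum
    for (id in names(mods)[mods == "M1"]) {
      others <- setdiff(names(mods)[mods == "M1"], id)
      expect_equal(unname(kk$kim[id]), sum(adj[id, others]))
    }
    expect_true(all(is.na(kk$kim[mods == "grey"])))
    # 2-member module: each member's kIM is their mutual adjacency
    m2 <- setNames(c("A", "A"), rownames(pe$x)[1:2])
    kk3 <- kme_kim(pe$x[1:2, ], adj[1:2, 1:2], m2,
                   module_eigengenes(pe$x[1:2, ], m2))
    expect_equal(unname(kk3$kim[1]), adj[1, 2])
  })
})

test_that("hub calls enforce membership, connectivity and significance", {
  withr::with_seed(86, {
    n_samp <- 30
    trait <- as.numeric(seq_len(n_samp) <= 6)
    traits <- cbind(heat_V3 = trait)
    lat <- 2 * trait + rnorm(n_samp, sd = 0.5)
    size <- 20
    x <- matrix(rnorm(size * n_samp, 5, 0.2), size, n_samp)
    for (i in 1:size) x[i, ] <- 5 + (0.8 + 0.01 * i) * lat +
      rnorm(n_samp, sd = 0.8)
    x[1, ] <- 5 + lat + rnorm(n_samp, sd = 0.05) # the planted hub
    rownames(x) <- c("hub", paste0("m", 2:size))
    colnames(x) <- paste0("s", seq_len(n_samp))
    mods <- setNames(rep("M1", size), rownames(x))
    adj <- soft_adjacency(x, 12)
    eg <- module_eigengenes(x, mods)
    kk <- kme_kim(x, adj, mods, eg)
    mt <- module_trait_correlation(eg, traits)
    gs <- module_trait_correlation(x, traits)
    hubs <- find_hubs(mods, kk$kme, kk$kim, gs, mt)
    expect_lte(nrow(hubs), ceiling(0.1 * size))
    expect_true("hub" %in% hubs$transcript_id)
    expect_true(all(hubs$kme > 0.9))
    expect_true(all(hubs$gs_p < 0.01))
    # a kME of 0.85 disqualifies regardless of connectivity
    strict <- find_hubs(mods, pmin(kk$kme, 0.85), kk$kim, gs, mt)
    expect_equal(nrow(strict), 0L)
  })
})

test_that("build_network wires the stages together deterministically", {
  withr::with_seed(87, {
    pe <- planted_expr(n_mod = 2, size = 8, n_bg = 10, n_samp = 24)
    counts <- round(2^pe$x)
    trait <- cbind(heat_V3 = as.numeric(seq_len(24) <= 8))
    rownames(trait) <- colnames(counts)
    net <- build_network(counts, trait,
                         network_config(min_module_size = 5))
    expect_s3_class(glance(net), "tbl_df")
    expect_true(all(net$hubs$transcript_id %in%
                      names(net$modules)[net$modules != "grey"]))
    ed <- network_edges(net, min_tom = 0.05)
    expect_true(all(ed$weight >= 0.05))
    td <- tidy(net)
    expect_equal(nrow(td), nrow(net$expr))
  })
})
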