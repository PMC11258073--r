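test_that("label preprocessing ignores distal arteries and boundary shells", {
  # aorta block plus an LM tube extending 40 mm from it at 1 mm spacing
  lab <- array(0L, dim = c(9, 15, 60))
  lab[3:7, 3:13, 3:13] <- 1L
  lab[4:6, 7:9, 14:54] <- 2L
  m <- label_mask(lab, c(1, 1, 1))
  pp <- preprocess_labels(m, cutoff_mm = 20)
  # brute-force distance of every LM voxel from the aorta voxel set
  av <- which(lab == 1L, arr.ind = TRUE)
  lm <- which(lab == 2L, arr.ind = TRUE)
  d <- apply(lm, 1, function(v)
    sqrt(min(colSums((t(av) - v)^2))))
  far <- lm[d > 20, , drop = FALSE]
  near_interior <- lm[d <= 20 & lm[, 2] == 8, , drop = FALSE]
  expect_true(all(pp$labels[far] == 255L))
  # interior (non-shell) proximal LM voxels keep their label
  keep <- pp$labels[near_interior] == 2L
  expect_true(any(keep))
  # aorta interior is untouched
  expect_true(all(pp$labels[5, 5:11, 5:11] == 1L))
})

test_that("one-voxel-thin structures are entirely ignored", {
  lab <- array(0L, dim = c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 1L
  lab[5, 7, 3:6] <- 2L           # thin LM sheet, 1 voxel thick
  pp <- preprocess_labels(label_mask(lab, c(1, 1, 1)), cutoff_mm = Inf)
  expect_true(all(pp$labels[lab == 2L] == 255L))
})

test_that("infinite cutoff leaves only boundary shells ignored", {
  p <- generate_phantom(toy_phantom_spec(seed = 5, noise_sd = 0))
  pp_inf <- preprocess_labels(p$labels, cutoff_mm = Inf)
  pp_20 <- preprocess_labels(p$labels, cutoff_mm = 20)
  n_inf <- sum(pp_inf$labels == 255L)
  n_20 <- sum(pp_20$labels == 255L)
  expect_gt(n_inf, 0)
  expect_gte(n_20, n_inf)   # the distance rule can only add ignores
  expect_error(preprocess_labels(blank_mask()), "no aorta")
})

test_that("postprocess keeps the largest component and fills holes", {
  lab <- array(0L, dim = c(12, 12, 12))
  lab[2:11, 2:11, 2:8] <- 1L            # big block: 10*10*7 = 700
  lab[1, 1, 11:12] <- 1L                # small satellite: 2 voxels
  lab[5:7, 5:7, 4:5] <- 0L              # sealed internal cavity
  pp <- postprocess(label_mask(lab, c(1, 1, 1)))
  expect_true(all(pp$labels[1, 1, 11:12] == 0L))      # satellite removed
  expect_true(all(pp$labels[5:7, 5:7, 4:5] == 1L))    # cavity filled
})

test_that("postprocess ties keep the lexicographically first component", {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[8:9, 8:9, 8:9] <- 1L      # 8 voxels, min index (8,8,8)
  lab[2:3, 2:3, 2:3] <- 1L      # 8 voxels, min index (2,2,2)
  pp <- postprocess(label_mask(lab, c(1, 1, 1)))
  # brute-force enumeration: both components have 8 voxels, the kept one
  # must contain (2,2,2)
  expect_identical(sum(pp$labels == 1L), 8L)
  expect_identical(pp$labels[2, 2, 2], 1L)
  expect_identical(pp$labels[8, 8, 8], 0L)
})

test_that("postprocess is idempotent on noisy random masks", {
  set.seed(8)
  for (i in 1:3) {
    lab <- array(sample(c(0L, 0L, 1L, 2L, 3L), 14^3, replace = TRUE),
                 dim = c(14, 14, 14))
    m <- label_mask(lab, c(1, 1, 1))
    once <- postprocess(m)
    twice <- postprocess(once)
    expect_identical(twice$labels, once$labels)
  }
})

test_that("dice follows its closed form and edge conventions", {
  a <- blank_mask(); b <- blank_mask()
  expect_identical(dice(a, b, "aorta"), 1)            # both empty
  a$labels[1:5, 1, 1] <- 1L
  expect_identical(dice(a, b, "aorta"), 0)            # disjoint
  b$labels[3:7, 1, 1] <- 1L
  expect_equal(dice(a, b, "aorta"), 2 * 3 / (5 + 5))  # overlap 3
  expect_error(dice(a, label_mask(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "shapes differ")
})

test_that("learning-rate schedule halves after 5 flat epochs and stops after 10", {
  s <- scheduler_init(1e-4, 0.5, 5L, 10L)
  for (i in 1:5) s <- scheduler_step(s, 1.0)
  # first step sets the best; epochs 2-5 count 4 flat epochs
  expect_equal(s$lr, 1e-4)
  s <- scheduler_step(s, 1.0)               # 5th flat epoch
  expect_equal(s$lr, 5e-5)
  expect_false(s$stop)
  for (i in 1:5) s <- scheduler_step(s, 1.0)
  expect_true(s$stop)                       # 10 epochs without decrease

  # a strict decrease resets both counters
  s2 <- scheduler_init(1e-4, 0.5, 5L, 10L)
  for (i in 1:4) s2 <- scheduler_step(s2, 1.0)
  s2 <- scheduler_step(s2, 0.5)
  for (i in 1:4) s2 <- scheduler_step(s2, 0.5)
  expect_equal(s2$lr, 1e-4)
  expect_false(s2$stop)
})

test_that("U-Net gradients match finite differences", {
  net <- unet_init(levels = 2L, width = 2L, seed = 3)
  set.seed(42)
  x <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8, 1))
  lab <- array(sample(c(0:3, 255L), 512, replace = TRUE), dim = c(8, 8, 8))
  fwd <- unet_forward(net, x, train = TRUE, dropout_rate = 0)
  ce <- softmax_ce_ignore(fwd$logits, lab, want_grad = TRUE)
  g <- unet_backward(net, fwd$cache, ce$dlogits)
  loss_at <- function(params) {
    net2 <- net; net2$params <- params
    softmax_ce_ignore(unet_forward(net2, x)$logits, lab)$loss
  }
  eps <- 1e-5
  for (nm in c("enc1_c1_W", "enc2_c2_g", "dec1_c2_W", "final_W")) {
    i <- 1L
    pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-5)
  }
})

test_that("ignored voxels contribute no loss and no gradient", {
  net <- unet_init(levels = 2L, width = 2L, seed = 5)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8, 1))
  lab <- array(sample(0:3, 512, replace = TRUE), dim = c(8, 8, 8))
  ign <- sample(512, 200)
  lab[ign] <- 255L
  fwd <- unet_forward(net, x, train = TRUE, dropout_rate = 0)
  ce1 <- softmax_ce_ignore(fwd$logits, lab, want_grad = TRUE)
  g1 <- unet_backward(net, fwd$cache, ce1$dlogits)
  # perturbing logits at ignored voxels must leave the loss unchanged
  logits2 <- fwd$logits
  m2 <- matrix(logits2, ncol = 4)
  m2[ign, ] <- m2[ign, ] + rnorm(length(ign) * 4, 0, 10)
  ce2 <- softmax_ce_ignore(array(m2, dim = dim(logits2)), lab)
  expect_identical(ce1$loss, ce2$loss)
  dl <- matrix(ce1$dlogits, ncol = 4)
  expect_true(all(dl[ign, ] == 0))
  expect_true(all(vapply(g1, function(q) all(is.finite(q)), TRUE)))
})
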