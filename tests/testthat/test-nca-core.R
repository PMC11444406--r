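zero_rule <- function(type = "fine", ...) {
  r <- nca_rule(type, n_hidden = 4, hidden_width = 4, ...)
  r$params <- lapply(r$params, function(p) p * 0)
  r$params$gamma <- r$params$gamma + 1
  r
}

rand_grid <- function(size = 12, seed = 1, n_hidden = 4) {
  withr::with_seed(seed, {
    g <- cell_grid(matrix(stats::runif(size^2), size), n_hidden = n_hidden)
    g$state[, -1] <- stats::rnorm(length(g$state[, -1]), sd = 0.3)
    g
  })
}

test_that("rule construction validates its configuration", {
  expect_error(nca_rule("fine", kernel = 4), "invalid config")
  expect_error(nca_rule("fine", fire_rate = 0), "invalid config")
  expect_error(nca_rule("fine", fire_rate = 1.2), "invalid config")
  r <- nca_rule("coarse")
  expect_identical(c(r$k, r$k2), c(7L, 3L))
  expect_identical(r$C, 18L)
})

test_that("zero weights produce a zero update field", {
  g <- rand_grid()
  U <- conv_base_block(g, zero_rule("fine"))
  expect_equal(max(abs(U)), 0)
  U2 <- nca_block(g, zero_rule("coarse"))
  expect_equal(max(abs(U2)), 0)
})

test_that("update fields are local: perturbations stay within the kernel radius", {
  for (k in c(3L, 7L)) {
    withr::with_seed(k, {
      r <- nca_rule("fine", kernel = k, n_hidden = 4, hidden_width = 6)
      r$params$Wo <- matrix(stats::rnorm(length(r$params$Wo), sd = 0.3),
                            nrow(r$params$Wo))
    })
    g <- rand_grid(15, seed = 2)
    U1 <- conv_base_block(g, r)
    g2 <- g
    g2$state[8 + (8 - 1) * 15, 2] <- g2$state[8 + (8 - 1) * 15, 2] + 1
    U2 <- conv_base_block(g2, r)
    diff <- apply(abs(U2 - U1), c(1, 2), max)
    touched <- which(diff > 1e-12, arr.ind = TRUE)
    expect_gt(nrow(touched), 0)
    cheb <- pmax(abs(touched[, 1] - 8), abs(touched[, 2] - 8))
    expect_lte(max(cheb), k %/% 2)
  }
})

test_that("the fused coarse block has receptive-field radius 4", {
  withr::with_seed(5, {
    r <- nca_rule("coarse", n_hidden = 4, hidden_width = 6)
    r$params$W2 <- matrix(stats::rnorm(length(r$params$W2), sd = 0.3),
                          nrow(r$params$W2))
  })
  g <- rand_grid(17, seed = 3)
  U1 <- nca_block(g, r)
  g2 <- g
  g2$state[9 + (9 - 1) * 17, 2] <- g2$state[9 + (9 - 1) * 17, 2] + 1
  U2 <- nca_block(g2, r)
  diff <- apply(abs(U2 - U1), c(1, 2), max)
  touched <- which(diff > 1e-12, arr.ind = TRUE)
  expect_lte(max(pmax(abs(touched[, 1] - 9), abs(touched[, 2] - 9))), 4)
})

test_that("eval-mode batch norm with unit stats reduces to ReLU(Dense(conv))", {
  withr::with_seed(7, r <- nca_rule("fine", kernel = 3, n_hidden = 2,
                                    hidden_width = 3))
  r$params$Wo <- matrix(stats::rnorm(length(r$params$Wo)), nrow(r$params$Wo))
  r$stats$default <- list(mean = numeric(3), var = rep(1, 3))
  g <- rand_grid(5, seed = 4, n_hidden = 2)
  U <- conv_base_block(g, r)
  # independent dense-layer oracle: explicit loops over pixels and offsets
  S <- grid_array(g)
  C <- dim(S)[3]
  oracle <- array(0, dim(S))
  for (i in 1:5) for (j in 1:5) {
    acc <- numeric(C)
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5) S[ii, jj, ] else
        numeric(C)
      off <- (di + 1) + (dj + 1) * 3 + 1
      for (co in seq_len(C)) {
        rows <- (co - 1) * 9 + off
        acc <- acc + v[co] * r$params$Wp[rows, ]
      }
    }
    d <- as.vector(acc %*% r$params$Wd) + r$params$bd
    relu <- pmax(d, 0)
    oracle[i, j, ] <- as.vector(relu %*% r$params$Wo) + r$params$bo
  }
  expect_equal(U, oracle, tolerance = 1e-4)
})

test_that("stochastic firing semantics at the fire-rate extremes", {
  withr::with_seed(1, r <- nca_rule("fine", n_hidden = 4, hidden_width = 4))
  r$params$bo <- rep(0.5, r$C)   # guarantee a non-zero update everywhere
  g <- rand_grid(16, seed = 6)
  # fire rate -> 0 limit: no cell fires, grid unchanged
  r0 <- r; r0$fire_rate <- 1e-12
  expect_identical(withr::with_seed(1, nca_step(g, r0))$state, g$state)
  # fire rate 1: deterministic, grid' = grid + update everywhere (hidden ch.)
  r1 <- r; r1$fire_rate <- 1
  U <- conv_base_block(g, r)
  s1 <- withr::with_seed(1, nca_step(g, r1))$state
  s2 <- withr::with_seed(2, nca_step(g, r1))$state
  expect_identical(s1, s2)
  expect_equal(s1[, -1], g$state[, -1] +
                 matrix(U, nrow(g$state), g$C)[, -1])
})

test_that("fire fraction concentrates around the fire rate", {
  withr::with_seed(2, r <- nca_rule("fine", n_hidden = 4, hidden_width = 4))
  r$params$bo <- rep(1, r$C)
  g <- rand_grid(64, seed = 7)
  fracs <- withr::with_seed(10, vapply(1:10, function(i) {
    g2 <- nca_step(g, r)
    mean(abs(g2$state[, 3] - g$state[, 3]) > 1e-12)
  }, numeric(1)))
  expect_gt(mean(fracs), 0.45)
  expect_lt(mean(fracs), 0.55)
})

test_that("iteration composes and preserves the input channel", {
  withr::with_seed(3, r <- nca_rule("fine", n_hidden = 4, hidden_width = 4))
  r$params$Wo <- matrix(stats::rnorm(length(r$params$Wo), sd = 0.2),
                        nrow(r$params$Wo))
  g <- rand_grid(10, seed = 8)
  expect_identical(nca_run(g, r, 0)$state, g$state)
  ab <- withr::with_seed(5, { x <- nca_run(g, r, 2); nca_run(x, r, 3) })
  once <- withr::with_seed(5, nca_run(g, r, 5))
  expect_identical(ab$state, once$state)
  expect_identical(once$state[, 1], g$state[, 1])
  expect_error(nca_run(g, r, -1), "invalid argument")
  # determinism with fire rate 1
  r$fire_rate <- 1
  expect_identical(withr::with_seed(1, nca_run(g, r, 10))$state,
                   withr::with_seed(9, nca_run(g, r, 10))$state)
})

test_that("analytic gradients match finite differences end to end", {
  withr::with_seed(42, {
    mc <- model_config(n_hidden = 3, hidden_width = 4, steps_coarse = 2,
                       steps_fine = 2, n_levels = 1, patch_cap = 8,
                       sgb_sp_area = 16, use_sgb = TRUE, seed = 9)
    model <- new_model(mc)
    model$clf$w <- stats::rnorm(model$coarse$C, sd = 0.3)
    phs <- lapply(1:2, function(i)
      generate_phantom(phantom_spec(height = 16, width = 16,
                                    radius_range = c(3, 5), seed = i)))
    imgs <- lapply(phs, function(p) rescale_unit(p$image))
    masks <- lapply(phs, function(p) p$mask)
    ts <- with_seed(7, train_step(model, imgs, masks))
    paths <- list(c("clf", "w"), c("fine", "Wp"), c("fine", "Wd"),
                  c("fine", "gamma"), c("fine", "Wo"), c("coarse", "W1"),
                  c("coarse", "gamma"), c("coarse", "W2"))
    for (pp in paths) {
      obj <- if (pp[1] == "clf") model$clf[[pp[2]]] else
        model[[pp[1]]]$params[[pp[2]]]
      for (idx in sample(length(obj), 2)) {
        eps <- 1e-5
        bump <- function(m, delta) {
          if (pp[1] == "clf") m$clf[[pp[2]]][idx] <- m$clf[[pp[2]]][idx] + delta
          else m[[pp[1]]]$params[[pp[2]]][idx] <-
              m[[pp[1]]]$params[[pp[2]]][idx] + delta
          m
        }
        num <- (with_seed(7, train_step(bump(model, eps), imgs, masks))$loss -
                  with_seed(7, train_step(bump(model, -eps), imgs, masks))$loss) /
          (2 * eps)
        ana <- if (pp[1] == "clf") ts$grads$clf[[pp[2]]][idx] else
          ts$grads[[pp[1]]][[pp[2]]][idx]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste(pp, collapse = "."))
      }
    }
  })
})
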