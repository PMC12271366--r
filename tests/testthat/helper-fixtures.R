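## Shared fixture builders (built in code, cached across tests in one run).

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## a rendered, noisy, segmented straight fiber (width 4, length 120 px)
fixture_straight_fiber <- function() {
  get_fixture("straight_fiber", function() {
    cl <- cbind(x = 60 + (0:119) * cos(0.3), y = 60 + (0:119) * sin(0.3))
    cv <- render_fiber(cl, 4, 400, matrix(0, 256, 256))
    noisy <- with_seed_test(9, cv + matrix(abs(rnorm(256^2, 20, 5)), 256))
    seg <- segment_collagen_pipeline(list(noisy))
    list(truth = list(length_px = 120, width_px = 4, angle_deg = 0.3 * 180 / pi),
         canvas = cv, noisy = noisy, seg = seg)
  })
}

## random 8x8 discretized toys for oracle-equivalence checks
random_toys <- function(n, seed = 42, levels = c(4, 8, 256)) {
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    ng <- sample(levels, 1)
    img <- matrix(sample(0:(ng - 1), 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) > 0.25, 8, 8)
    if (!any(mask)) mask[3, 3] <- TRUE
    discretized_image(img, mask, sample(c("SHG", "TPEF"), 1))
  }))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_histogram <- function(nlev = 64, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(nlev, lambda = rexp(nlev, 1 / 20))
  if (sum(counts > 0) < 2) counts[c(1, nlev)] <- counts[c(1, nlev)] + 1
  counts
}
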