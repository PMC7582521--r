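# fixtures shared across test files (all built in code)

default_grid <- make_ramp_grid()
grid_step <- function(a, b) abs(log10(a / b)) * 20  # distance in grid steps

# nearest default-protocol grid point to a target stress
on_grid <- function(target) default_grid[which.min(abs(log10(default_grid / target)))]

# parameter lattice used for recovery tests
recovery_lattice <- expand.grid(K0 = c(10, 50, 200), m = c(1, 1.5, 2),
                                sigma0 = c(0.5, 2, 10))

# horizontal bar of given odd width spanning a square image
bar_image <- function(size = 64, width = 5, row = NULL) {
  row <- row %||% (size %/% 2)
  m <- matrix(FALSE, size, size)
  half <- (width - 1) %/% 2
  m[(row - half):(row + half), ] <- TRUE
  fiber_image(m)
}

# square annulus (fiber ring) with a single enclosed pore
annulus_image <- function(size = 64, outer = c(20, 44), thickness = 5) {
  m <- matrix(FALSE, size, size)
  o1 <- outer[1]; o2 <- outer[2]; t <- thickness
  m[o1:o2, o1:o2] <- TRUE
  m[(o1 + t):(o2 - t), (o1 + t):(o2 - t)] <- FALSE
  fiber_image(m)
}

crossing_bars_image <- function(size = 64, width = 5) {
  m1 <- as_mask_local(bar_image(size, width))
  m2 <- t(m1)
  fiber_image(m1 | m2)
}

as_mask_local <- function(img) matrix(as.logical(img), nrow(img), ncol(img))

`%||%` <- function(a, b) if (is.null(a)) b else a
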