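# Internal helpers shared across modules.

# Scalar/numeric argument checks ------------------------------------------

stop_if_not_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All generators route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stop_if_not_scalar(seed, "seed")
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Empty localization table with the canonical column set.
empty_localization_table <- function() {
  data.frame(
    frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
    photons = numeric(0), sigma_nm = numeric(0), background = numeric(0),
    precision_nm = numeric(0)
  )
}

loc_table_columns <- c(
  "frame", "x_nm", "y_nm", "photons", "sigma_nm", "background",
  "precision_nm"
)

check_localization_table <- function(table) {
  if (!is.data.frame(table)) {
    stop("localization table must be a data.frame", call. = FALSE)
  }
  missing <- setdiff(c("frame", "x_nm", "y_nm"), names(table))
  if (length(missing)) {
    stop("localization table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

# Peak pixel value produced by a single localization after rendering and
# Gaussian blurring; used as the unit for "localization-equivalent"
# thresholds. Computed empirically with the same blur backend as
# render_map() so kernel discretization is accounted for.
impulse_peak <- function(blur_sigma_px) {
  if (blur_sigma_px <= 0) return(1)
  n <- max(17L, 2L * ceiling(4 * blur_sigma_px) + 1L)
  delta <- matrix(0, n, n)
  delta[(n + 1L) / 2L, (n + 1L) / 2L] <- 1
  max(EBImage::gblur(delta, sigma = blur_sigma_px))
}
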