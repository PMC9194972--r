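# Gaussian smoothing with replicate boundary handling; sigma in pixels.
# The brush radius is capped so tiny (test-sized) matrices stay filterable.
gauss_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  radius <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  max_odd <- function(k) if (k %% 2L == 0L) k - 1L else k
  radius <- min(radius, max_odd(min(dim(mat))))
  if (radius < 3L) return(mat)
  out <- EBImage::gblur(mat, sigma = sigma_px, radius = radius,
                        boundary = "replicate")
  # the FFT-based convolution can leave values a few ulp below zero
  out[out < 0] <- 0
  out
}
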