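# Stride-1, same-padding 2D cross-correlation and its adjoints, built on a
# cached im2col index so each application is a single matrix product.
# Kernels must have odd height/width so that "same" padding is symmetric.

.conv_cache <- new.env(parent = emptyenv())

#' @noRd
patch_index <- function(in_ch, h, w, kh, kw) {
  key <- paste(in_ch, h, w, kh, kw, sep = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  hp <- h + 2L * ph
  # patch rows ordered channel-fastest, then kernel row, then kernel col,
  # matching the column-major collapse of a (out, in, kh, kw) kernel array
  pr <- expand.grid(c = seq_len(in_ch), a = seq_len(kh), b = seq_len(kw))
  oc <- expand.grid(i = seq_len(h), j = seq_len(w))
  n_pr <- nrow(pr)
  n_oc <- nrow(oc)
  # padded flat index of (c, r, col) = c + in_ch*((r-1) + hp*(col-1));
  # output (i, j) reads padded rows i..i+kh-1, cols j..j+kw-1
  row_term <- pr$c + in_ch * (pr$a - 1L + hp * (pr$b - 1L))
  col_term <- in_ch * (oc$i - 1L + hp * (oc$j - 1L))
  idx <- matrix(rep(row_term, n_oc), n_pr, n_oc) +
    matrix(rep(col_term, each = n_pr), n_pr, n_oc)
  out <- list(idx = idx, ph = ph, pw = pw, hp = hp, wp = w + 2L * pw)
  .conv_cache[[key]] <- out
  out
}

#' @noRd
pad_input <- function(x, pi) {
  d <- dim(x)
  if (pi$ph == 0L && pi$pw == 0L) {
    return(x)
  }
  xp <- array(0, c(d[1], pi$hp, pi$wp))
  xp[, pi$ph + seq_len(d[2]), pi$pw + seq_len(d[3])] <- x
  xp
}

# x: (in_ch, h, w); kernel: (out_ch, in_ch, kh, kw) -> (out_ch, h, w)
#' @noRd
conv2d <- function(x, kernel) {
  kd <- dim(kernel)
  xd <- dim(x)
  stopifnot(length(kd) == 4L, length(xd) == 3L, kd[2] == xd[1],
            kd[3] %% 2L == 1L, kd[4] %% 2L == 1L)
  pi <- patch_index(xd[1], xd[2], xd[3], kd[3], kd[4])
  p <- matrix(pad_input(x, pi)[pi$idx], nrow(pi$idx))
  array(matrix(kernel, kd[1]) %*% p, c(kd[1], xd[2], xd[3]))
}

# adjoint of conv2d w.r.t. the input: correlation of g_out with the
# spatially flipped, channel-transposed kernel
#' @noRd
conv_input_grad <- function(kernel, g_out) {
  kd <- dim(kernel)
  kr <- aperm(kernel[, , rev(seq_len(kd[3])), rev(seq_len(kd[4])),
                     drop = FALSE], c(2, 1, 3, 4))
  conv2d(g_out, kr)
}

# adjoint of conv2d w.r.t. the kernel
#' @noRd
conv_weight_grad <- function(x, g_out, kh, kw) {
  xd <- dim(x)
  gd <- dim(g_out)
  pi <- patch_index(xd[1], xd[2], xd[3], kh, kw)
  p <- matrix(pad_input(x, pi)[pi$idx], nrow(pi$idx))
  g <- matrix(g_out, gd[1]) %*% t(p)
  array(g, c(gd[1], xd[1], kh, kw))
}

# number of (output position x output channel) synapses each input position
# feeds under same padding; used for event-driven operation counting
#' @noRd
conv_fanout_map <- function(h, w, kh, kw, out_ch) {
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  rows <- pmin(h, seq_len(h) + ph) - pmax(1L, seq_len(h) - ph) + 1L
  cols <- pmin(w, seq_len(w) + pw) - pmax(1L, seq_len(w) - pw) + 1L
  outer(rows, cols) * out_ch
}
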