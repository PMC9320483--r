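# Reduced U-Net: ResNet-style encoder, decoder with exactly two up-sampling
# levels, two-channel sigmoid output at 1/8 of the input resolution.
#
# The network is represented as a static op graph (conv / relu / maxpool /
# nearest-up2 / concat / add / sigmoid) over numbered buffers, with exact
# adjoints for every op, so the same machinery runs both presets.

#' Network configuration
#'
#' @param input_side input tile side in px; must be divisible by 32
#'   (default 1024).
#' @param preset `"paper"` for the ResNet34-style encoder (3/4/6/3 basic
#'   blocks, widths 64/128/256/512) or `"small"` for a light 4-stage encoder
#'   (widths 16/32/64/128) suitable for CPU-scale experiments.
#' @return an object of class `bdsk_network_config`. The output stride is 8
#'   and the output has two channels (BD, SK) for either preset.
#' @export
network_config <- function(input_side = 1024L, preset = c("paper", "small")) {
  preset <- match.arg(preset)
  input_side <- as.integer(input_side)
  if (input_side %% 32L != 0L) stop("input side must be divisible by 32")
  structure(list(input_side = input_side, preset = preset,
                 output_stride = 8L, out_channels = 2L, up_levels = 2L),
            class = "bdsk_network_config")
}

# --- graph builder -----------------------------------------------------------

g_new <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- list(); e$nbuf <- 1L; e$specs <- list()
  e
}

g_buf <- function(G) { G$nbuf <- G$nbuf + 1L; G$nbuf }

g_conv <- function(G, a, name, cin, cout, k = 3L, stride = 1L) {
  pad <- (k - 1L) %/% 2L
  out <- g_buf(G)
  G$ops[[length(G$ops) + 1L]] <- list(op = "conv", a = a, out = out,
                                      param = name, k = k, stride = stride,
                                      pad = pad)
  G$specs[[name]] <- c(k = k, cin = cin, cout = cout)
  out
}

g_simple <- function(G, op, a, b = NULL, k = NULL, stride = NULL, pad = NULL) {
  out <- g_buf(G)
  G$ops[[length(G$ops) + 1L]] <- list(op = op, a = a, b = b, out = out,
                                      k = k, stride = stride, pad = pad)
  out
}

g_conv_relu <- function(G, a, name, cin, cout, k = 3L, stride = 1L) {
  g_simple(G, "relu", g_conv(G, a, name, cin, cout, k, stride))
}

g_resblock <- function(G, a, name, cin, cout, stride = 1L) {
  y <- g_conv_relu(G, a, paste0(name, "_c1"), cin, cout, 3L, stride)
  y <- g_conv(G, y, paste0(name, "_c2"), cout, cout, 3L, 1L)
  idn <- if (stride == 1L && cin == cout) a else
    g_conv(G, a, paste0(name, "_proj"), cin, cout, 1L, stride)
  g_simple(G, "relu", g_simple(G, "add", y, idn))
}

build_graph_small <- function() {
  G <- g_new()
  w <- c(16L, 32L, 64L, 128L)
  x <- g_conv_relu(G, 1L, "stem", 3L, w[1], 3L, 2L)             # /2
  x <- g_conv_relu(G, x, "s1a", w[1], w[1], 3L, 2L)             # /4
  x <- g_conv_relu(G, x, "s1b", w[1], w[1])
  x <- g_conv_relu(G, x, "s2a", w[1], w[2], 3L, 2L)             # /8
  skip8 <- g_conv_relu(G, x, "s2b", w[2], w[2])
  x <- g_conv_relu(G, skip8, "s3a", w[2], w[3], 3L, 2L)         # /16
  skip16 <- g_conv_relu(G, x, "s3b", w[3], w[3])
  x <- g_conv_relu(G, skip16, "s4a", w[3], w[4], 3L, 2L)        # /32
  x <- g_conv_relu(G, x, "s4b", w[4], w[4])
  G$bottleneck <- x
  x <- g_simple(G, "up2", x)                                     # /16
  x <- g_simple(G, "concat", x, skip16)
  x <- g_conv_relu(G, x, "d1a", w[4] + w[3], w[3])
  x <- g_conv_relu(G, x, "d1b", w[3], w[3])
  x <- g_simple(G, "up2", x)                                     # /8
  x <- g_simple(G, "concat", x, skip8)
  x <- g_conv_relu(G, x, "d2a", w[3] + w[2], w[2])
  x <- g_conv_relu(G, x, "d2b", w[2], w[2])
  x <- g_conv(G, x, "head", w[2], 2L, 1L, 1L)
  G$out <- g_simple(G, "sigmoid", x)
  G
}

build_graph_paper <- function() {
  G <- g_new()
  w <- c(64L, 128L, 256L, 512L)
  nblocks <- c(3L, 4L, 6L, 3L)
  x <- g_conv_relu(G, 1L, "stem", 3L, w[1], 7L, 2L)              # /2
  x <- g_simple(G, "pool", x, k = 3L, stride = 2L, pad = 1L)     # /4
  skips <- list()
  cin <- w[1]
  for (st in 1:4) {
    for (bl in seq_len(nblocks[st])) {
      stride <- if (st > 1L && bl == 1L) 2L else 1L
      x <- g_resblock(G, x, sprintf("st%d_b%d", st, bl), cin, w[st], stride)
      cin <- w[st]
    }
    skips[[st]] <- x
  }
  G$bottleneck <- x                                              # /32
  x <- g_simple(G, "up2", x)                                     # /16
  x <- g_simple(G, "concat", x, skips[[3]])
  x <- g_conv_relu(G, x, "d1a", w[4] + w[3], w[3])
  x <- g_conv_relu(G, x, "d1b", w[3], w[3])
  x <- g_simple(G, "up2", x)                                     # /8
  x <- g_simple(G, "concat", x, skips[[2]])
  x <- g_conv_relu(G, x, "d2a", w[3] + w[2], w[2])
  x <- g_conv_relu(G, x, "d2b", w[2], w[2])
  x <- g_conv(G, x, "head", w[2], 2L, 1L, 1L)
  G$out <- g_simple(G, "sigmoid", x)
  G
}

# Side length of every buffer for a given input side (no tensors touched).
trace_sides <- function(G, input_side) {
  side <- rep(NA_integer_, G$nbuf)
  side[1] <- input_side
  for (op in G$ops) {
    side[op$out] <- switch(op$op,
      conv = (side[op$a] + 2L * op$pad - op$k) %/% op$stride + 1L,
      pool = (side[op$a] + 2L * op$pad - op$k) %/% op$stride + 1L,
      up2 = 2L * side[op$a],
      side[op$a]
    )
  }
  side
}

#' Build the segmentation network
#'
#' For the paper preset at input side 1024 the encoder bottleneck is 32 px and
#' the output is 128 px with two channels, i.e. one output pixel per 8 x 8
#' input region. Weights use He-normal initialisation; biases start at zero.
#'
#' @param cfg a [network_config()].
#' @param seed seed for weight initialisation.
#' @return an object of class `bdsk_network` with elements `cfg`, `params` and
#'   `shapes` (`input_side`, `bottleneck_side`, `output_side`, `out_channels`).
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "bdsk_network_config"))
  G <- if (cfg$preset == "paper") build_graph_paper() else build_graph_small()
  sides <- trace_sides(G, cfg$input_side)
  params <- with_seed(seed, {
    lapply(G$specs, function(sp) {
      fanin <- sp["k"]^2 * sp["cin"]
      list(w = matrix(rnorm(fanin * sp["cout"], 0, sqrt(2 / fanin)),
                      nrow = fanin, ncol = sp["cout"]),
           b = numeric(sp["cout"]))
    })
  })
  structure(list(
    cfg = cfg,
    ops = G$ops,
    nbuf = G$nbuf,
    out_id = G$out,
    params = params,
    shapes = list(input_side = cfg$input_side,
                  bottleneck_side = sides[G$bottleneck],
                  output_side = sides[G$out],
                  out_channels = cfg$out_channels)
  ), class = "bdsk_network")
}

#' @export
print.bdsk_network <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), 0))
  cat(sprintf(
    "Reduced U-Net (%s preset): input %d px -> bottleneck %d px -> output %d px x %d channels\n%d conv layers, %s parameters\n",
    x$cfg$preset, x$shapes$input_side, x$shapes$bottleneck_side,
    x$shapes$output_side, x$shapes$out_channels,
    length(x$params), format(np, big.mark = ",")))
  invisible(x)
}

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# Forward pass; keeps all buffers (needed for backward).
net_forward <- function(net, x) {
  stopifnot(length(dim(x)) == 3)
  bufs <- vector("list", net$nbuf)
  caches <- vector("list", net$nbuf)
  bufs[[1L]] <- x - 0.5  # centre RGB inputs
  for (op in net$ops) {
    bufs[[op$out]] <- switch(op$op,
      conv = {
        p <- net$params[[op$param]]
        cpp_conv_fw(bufs[[op$a]], p$w, p$b, op$k, op$stride, op$pad)
      },
      relu = pmax(bufs[[op$a]], 0),
      pool = {
        r <- cpp_maxpool_fw(bufs[[op$a]], op$k, op$stride, op$pad)
        caches[[op$out]] <- r$argmax
        r$out
      },
      up2 = cpp_up2_fw(bufs[[op$a]]),
      concat = concat3(bufs[[op$a]], bufs[[op$b]]),
      add = bufs[[op$a]] + bufs[[op$b]],
      sigmoid = 1 / (1 + exp(-bufs[[op$a]]))
    )
  }
  list(out = bufs[[net$out_id]], bufs = bufs, caches = caches)
}

# Backward pass: gradient of a scalar loss wrt every parameter, given the
# gradient wrt the network output.
net_backward <- function(net, fwd, gout) {
  gbuf <- vector("list", net$nbuf)
  gbuf[[net$out_id]] <- gout
  grads <- list()
  acc <- function(id, val) {
    gbuf[[id]] <<- if (is.null(gbuf[[id]])) val else gbuf[[id]] + val
  }
  for (op in rev(net$ops)) {
    go <- gbuf[[op$out]]
    if (is.null(go)) next
    switch(op$op,
      conv = {
        p <- net$params[[op$param]]
        r <- cpp_conv_bw(fwd$bufs[[op$a]], p$w, go, op$k, op$stride, op$pad)
        if (is.null(grads[[op$param]])) {
          grads[[op$param]] <- list(w = r$gw, b = r$gb)
        } else {
          grads[[op$param]]$w <- grads[[op$param]]$w + r$gw
          grads[[op$param]]$b <- grads[[op$param]]$b + r$gb
        }
        acc(op$a, r$gx)
      },
      relu = acc(op$a, go * (fwd$bufs[[op$out]] > 0)),
      pool = {
        d <- dim(fwd$bufs[[op$a]])
        acc(op$a, cpp_maxpool_bw(go, fwd$caches[[op$out]], d[1], d[2], d[3]))
      },
      up2 = acc(op$a, cpp_up2_bw(go)),
      concat = {
        ca <- dim(fwd$bufs[[op$a]])[3]
        acc(op$a, go[, , seq_len(ca), drop = FALSE])
        acc(op$b, go[, , -seq_len(ca), drop = FALSE])
      },
      add = { acc(op$a, go); acc(op$b, go) },
      sigmoid = {
        s <- fwd$bufs[[op$out]]
        acc(op$a, go * s * (1 - s))
      }
    )
  }
  grads
}

#' Predict the heat maps for one tile
#'
#' @param model a `bdsk_network` (or a fitted `bdsk_model`).
#' @param tile side x side x 3 array matching the network's input side.
#' @param coord optional 0-based tile origin `c(x0, y0)` carried along for
#'   stitching.
#' @return an object of class `bdsk_tile_heatmap`: list with `probs`
#'   (side/8 x side/8 x 2 array, channel 1 = BD, channel 2 = SK), `coord`, and
#'   `stride_px` (8).
#' @export
predict_tile <- function(model, tile, coord = c(0L, 0L)) {
  net <- if (inherits(model, "bdsk_model")) model$network else model
  stopifnot(inherits(net, "bdsk_network"))
  d <- dim(tile)
  if (is.null(d) || length(d) != 3 || d[1] != net$cfg$input_side ||
      d[2] != net$cfg$input_side) {
    stop(sprintf("tile must be %d x %d x 3", net$cfg$input_side,
                 net$cfg$input_side))
  }
  out <- net_forward(net, tile)$out
  structure(list(probs = out, coord = as.integer(coord),
                 stride_px = net$cfg$output_stride),
            class = "bdsk_tile_heatmap")
}
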