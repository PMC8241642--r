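#' Siamese network configuration
#'
#' Hyperparameters of the weight-sharing twin-tower 3D residual network.
#' The `"full"` preset is an 18-weighted-layer residual tower (stem
#' convolution, four stages of two residual blocks, global average
#' pooling, linear projection to the 1024-entry embedding) for 48^3
#' cubes. The `"tiny"` preset shrinks channels and depth for 16^3 cubes
#' and is the desk-scale test default. Training defaults: plain SGD,
#' learning rate 0.01, weight decay 0.005, batch size 128, 16 epochs.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param embedding_dim embedding length (default 1024).
#' @param lr,weight_decay,batch_size,epochs SGD hyperparameters.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param input_n,stem_channels,stage_channels,stage_blocks,stage_strides
#'   architecture overrides (defaults come from the preset).
#' @return a `siamese_config` list.
#' @export
siamese_config <- function(preset = c("tiny", "full"),
                           embedding_dim = 1024L,
                           lr = 0.01, weight_decay = 0.005,
                           batch_size = 128L, epochs = 16L, seed = 1L,
                           input_n = NULL, stem_channels = NULL,
                           stage_channels = NULL, stage_blocks = NULL,
                           stage_strides = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(input_n = 48L, stem_channels = 64L,
         stage_channels = c(64L, 128L, 256L, 512L),
         stage_blocks = c(2L, 2L, 2L, 2L),
         stage_strides = c(1L, 2L, 2L, 2L))
  } else {
    list(input_n = 16L, stem_channels = 4L,
         stage_channels = c(4L, 8L),
         stage_blocks = c(1L, 1L),
         stage_strides = c(1L, 2L))
  }
  cfg <- list(preset = preset,
              input_n = input_n %||% def$input_n,
              stem_channels = stem_channels %||% def$stem_channels,
              stage_channels = stage_channels %||% def$stage_channels,
              stage_blocks = stage_blocks %||% def$stage_blocks,
              stage_strides = stage_strides %||% def$stage_strides,
              embedding_dim = as.integer(embedding_dim),
              lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed))
  stopifnot(cfg$embedding_dim > 0L, cfg$lr > 0, cfg$weight_decay >= 0,
            cfg$batch_size > 0L, cfg$epochs > 0L,
            length(cfg$stage_channels) == length(cfg$stage_blocks),
            length(cfg$stage_channels) == length(cfg$stage_strides))
  structure(cfg, class = "siamese_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

conv_init <- function(k, ci, co) {
  w <- array(rnorm(k^3 * ci * co, 0, sqrt(2 / (k^3 * ci))), c(k, k, k, ci, co))
  list(w = w, b = numeric(co))
}

#' Build a Siamese model
#'
#' Randomly initializes (He initialization, seeded) the shared tower and
#' the fully connected scoring layer. The two towers are structurally one
#' parameter set: every forward pass of either cube uses the same
#' weights.
#'
#' @param cfg a [siamese_config()].
#' @return a `siamese_model` with untrained parameters.
#' @export
siamese_build <- function(cfg) {
  stopifnot(inherits(cfg, "siamese_config"))
  params <- with_seed(cfg$seed, {
    stem <- c(conv_init(3L, 1L, cfg$stem_channels), stride = 2L)
    stages <- list()
    cin <- cfg$stem_channels
    for (s in seq_along(cfg$stage_channels)) {
      cout <- cfg$stage_channels[s]
      blocks <- list()
      for (b in seq_len(cfg$stage_blocks[s])) {
        stride <- if (b == 1L) cfg$stage_strides[s] else 1L
        blk <- list(conv1 = c(conv_init(3L, cin, cout), stride = stride),
                    conv2 = c(conv_init(3L, cout, cout), stride = 1L),
                    proj = NULL)
        if (stride != 1L || cin != cout) {
          blk$proj <- c(conv_init(1L, cin, cout), stride = stride)
        }
        blocks[[b]] <- blk
        cin <- cout
      }
      stages[[s]] <- blocks
    }
    clast <- cin
    fc <- list(W = matrix(rnorm(cfg$embedding_dim * clast, 0,
                                sqrt(2 / clast)),
                          cfg$embedding_dim, clast),
               b = numeric(cfg$embedding_dim))
    head <- list(w = rnorm(cfg$embedding_dim, 0,
                           sqrt(2 / cfg$embedding_dim)),
                 b = 0)
    list(stem = stem, stages = stages, fc = fc, head = head)
  })
  structure(list(config = cfg, params = params, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "siamese_model")
}

#' @export
print.siamese_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(rapply(x$params, length, how = "unlist")))
  cat(sprintf(paste0("<siamese_model> %s preset, input %d^3, embedding %d, ",
                     "%s parameters, %s\n"),
              cfg$preset, cfg$input_n, cfg$embedding_dim,
              format(np, big.mark = ","),
              if (x$trained) sprintf("trained (best epoch %d, val AUC %.3f)",
                                     x$best_epoch,
                                     max(x$history$val_auc, na.rm = TRUE))
              else "untrained"))
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

conv_fw <- function(layer, x) .conv3d_fw(x, layer$w, layer$b, layer$stride, 1L)
proj_fw <- function(layer, x) .conv3d_fw(x, layer$w, layer$b, layer$stride, 0L)

# Forward pass of the shared tower on a batch x: dim c(D,H,W,1,N).
# Returns list(embed = embedding_dim x N, cache) for backprop.
tower_forward <- function(params, x) {
  cache <- list()
  z <- conv_fw(params$stem, x)
  a <- pmax(z, 0)
  cache$stem <- list(x = x, z = z)
  for (s in seq_along(params$stages)) {
    for (b in seq_along(params$stages[[s]])) {
      blk <- params$stages[[s]][[b]]
      xin <- a
      z1 <- conv_fw(blk$conv1, xin)
      a1 <- pmax(z1, 0)
      z2 <- conv_fw(blk$conv2, a1)
      sk <- if (is.null(blk$proj)) xin else proj_fw(blk$proj, xin)
      zs <- z2 + sk
      a <- pmax(zs, 0)
      cache[[paste0("s", s, "b", b)]] <- list(xin = xin, z1 = z1, a1 = a1,
                                              zs = zs)
    }
  }
  d <- dim(a)
  nvox <- prod(d[1:3])
  gap <- matrix(colMeans(matrix(a, nvox)), d[4], d[5])
  embed <- params$fc$W %*% gap + params$fc$b
  cache$gap_in_dim <- d
  cache$gap <- gap
  list(embed = embed, cache = cache)
}

# Backward pass; returns parameter gradients (same structure as params).
tower_backward <- function(params, cache, gembed) {
  g <- list()
  g$fc <- list(W = gembed %*% t(cache$gap), b = rowSums(gembed))
  dgap <- t(params$fc$W) %*% gembed           # C x N
  d <- cache$gap_in_dim
  nvox <- prod(d[1:3])
  ga <- array(rep(as.numeric(dgap), each = nvox) / nvox, d)
  g$stages <- vector("list", length(params$stages))
  for (s in rev(seq_along(params$stages))) {
    g$stages[[s]] <- vector("list", length(params$stages[[s]]))
    for (b in rev(seq_along(params$stages[[s]]))) {
      blk <- params$stages[[s]][[b]]
      cc <- cache[[paste0("s", s, "b", b)]]
      gzs <- ga * (cc$zs > 0)
      bw2 <- .conv3d_bw(cc$a1, blk$conv2$w, gzs, blk$conv2$stride, 1L)
      gz1 <- bw2$gx * (cc$z1 > 0)
      bw1 <- .conv3d_bw(cc$xin, blk$conv1$w, gz1, blk$conv1$stride, 1L)
      gx <- bw1$gx
      gblk <- list(conv1 = list(w = bw1$gw, b = bw1$gb),
                   conv2 = list(w = bw2$gw, b = bw2$gb), proj = NULL)
      if (is.null(blk$proj)) {
        gx <- gx + gzs
      } else {
        bwp <- .conv3d_bw(cc$xin, blk$proj$w, gzs, blk$proj$stride, 0L)
        gx <- gx + bwp$gx
        gblk$proj <- list(w = bwp$gw, b = bwp$gb)
      }
      g$stages[[s]][[b]] <- gblk
      ga <- gx
    }
  }
  gz <- ga * (cache$stem$z > 0)
  bws <- .conv3d_bw(cache$stem$x, params$stem$w, gz, params$stem$stride, 1L)
  g$stem <- list(w = bws$gw, b = bws$gb)
  g
}

# Stack a list of n^3 cubes into a batch tensor dim c(n,n,n,1,N).
stack_cubes <- function(cubes) {
  n <- dim(cubes[[1]])[1]
  array(unlist(cubes, use.names = FALSE), c(n, n, n, 1L, length(cubes)))
}

#' Embed a cube with the shared tower
#'
#' @param model a `siamese_model`.
#' @param cube an `n^3` array matching the model's input size.
#' @return numeric vector of length `embedding_dim`.
#' @export
siamese_embed <- function(model, cube) {
  x <- stack_cubes(list(cube))
  drop(tower_forward(model$params, x)$embed)
}

# Batched scoring: list of pocs -> probabilities.
score_batch <- function(params, pocs, batch_size = 256L) {
  out <- numeric(length(pocs))
  i <- 1L
  while (i <= length(pocs)) {
    j <- min(i + batch_size - 1L, length(pocs))
    ea <- tower_forward(params, stack_cubes(lapply(pocs[i:j], `[[`, "cube_a")))$embed
    eb <- tower_forward(params, stack_cubes(lapply(pocs[i:j], `[[`, "cube_b")))$embed
    u <- abs(ea - eb)
    out[i:j] <- plogis(drop(crossprod(params$head$w, u)) + params$head$b)
    i <- j + 1L
  }
  out
}

#' Score a pair-of-cubes
#'
#' `p = sigmoid(FC(|embed(a) - embed(b)|))`: the abnormality probability
#' of the pair. Symmetric in its two cubes (the towers share weights and
#' the absolute difference is order-free), and constant over all
#' self-paired inputs (`cube_a == cube_b` implies a zero difference
#' vector, so every such pair scores `sigmoid(b_head)`).
#'
#' @param model a `siamese_model`.
#' @param poc a `poc` (or list with `cube_a`, `cube_b`).
#' @return probability in (0, 1).
#' @export
siamese_score <- function(model, poc) {
  stopifnot(identical(dim(poc$cube_a), dim(poc$cube_b)))
  score_batch(model$params, list(poc))
}

#' @export
predict.siamese_model <- function(object, pocs, ...) {
  if (inherits(pocs, "poc_dataset")) pocs <- pocs$pocs
  if (inherits(pocs, "poc")) pocs <- list(pocs)
  score_batch(object$params, pocs)
}

# Recursive SGD update with weight decay (skips stride fields and
# entries absent from the gradient tree).
sgd_update <- function(p, g, lr, wd) {
  if (is.list(p)) {
    keys <- names(p) %||% seq_along(p)
    for (k in keys) {
      if (identical(k, "stride") || is.null(p[[k]]) || is.null(g[[k]])) next
      p[[k]] <- sgd_update(p[[k]], g[[k]], lr, wd)
    }
    return(p)
  }
  p - lr * (g + wd * p)
}

#' Train a Siamese model
#'
#' Plain stochastic gradient descent on the weighted binary cross-entropy
#' of the pair scores, with inverse-class-frequency sample weights and
#' weight decay. After every epoch the validation AUC is logged; the
#' returned model carries the parameters of the best-validation-AUC
#' epoch. Fully seeded and deterministic on a fixed machine.
#'
#' @param model an untrained (or trained) `siamese_model`.
#' @param dataset a [poc_dataset()] with nonempty `train` and `val`
#'   splits and both classes in `train`.
#' @param quiet suppress per-epoch progress messages.
#' @return the trained `siamese_model` with `history` (per-epoch train
#'   loss and val AUC) and `best_epoch`.
#' @export
siamese_train <- function(model, dataset, quiet = TRUE) {
  cfg <- model$config
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "val")
  if (length(tr) == 0L || length(va) == 0L) {
    stop("train and val splits must be nonempty")
  }
  ytr <- dataset$labels[tr]
  if (length(unique(ytr)) < 2L) {
    stop("training split must contain both classes")
  }
  wtr <- dataset$weights[tr]
  params <- model$params
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_auc = NA_real_, val_loss = NA_real_)
  best <- list(auc = -Inf, loss = Inf, params = params, epoch = NA_integer_)
  epoch_seeds <- derive_seeds(cfg$seed + 7L, cfg$epochs)
  val_pocs <- dataset$pocs[va]
  yva <- dataset$labels[va]
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample(seq_along(tr)))
    total_loss <- 0
    total_w <- 0
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + cfg$batch_size - 1L, length(ord))
      bi <- ord[i:j]
      pocs <- dataset$pocs[tr[bi]]
      y <- ytr[bi]
      w <- wtr[bi]
      fa <- tower_forward(params, stack_cubes(lapply(pocs, `[[`, "cube_a")))
      fb <- tower_forward(params, stack_cubes(lapply(pocs, `[[`, "cube_b")))
      u <- abs(fa$embed - fb$embed)
      z <- drop(crossprod(params$head$w, u)) + params$head$b
      p <- plogis(z)
      eps <- 1e-12
      total_loss <- total_loss -
        sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
      total_w <- total_w + sum(w)
      dz <- w * (p - y) / sum(w)
      ghead <- list(w = drop(u %*% dz), b = sum(dz))
      du <- outer(params$head$w, dz)
      gea <- du * sign(fa$embed - fb$embed)
      ga <- tower_backward(params, fa$cache, gea)
      gb <- tower_backward(params, fb$cache, -gea)
      gtow <- add_grads(ga, gb)
      gtow$head <- ghead
      params <- sgd_update(params, gtow, cfg$lr, cfg$weight_decay)
      i <- j + 1L
    }
    hist$train_loss[ep] <- total_loss / total_w
    pv <- score_batch(params, val_pocs)
    eps <- 1e-12
    vloss <- -mean(yva * log(pv + eps) + (1 - yva) * log(1 - pv + eps))
    auc <- if (length(unique(yva)) == 2L) roc_auc(pv, yva) else NA_real_
    hist$val_auc[ep] <- auc
    hist$val_loss[ep] <- vloss
    # best validation AUC; equal AUCs tie-broken by validation loss
    crit <- if (is.na(auc)) -hist$train_loss[ep] else auc
    if (crit > best$auc || (crit == best$auc && vloss < best$loss)) {
      best <- list(auc = crit, loss = vloss, params = params, epoch = ep)
    }
    if (!quiet) {
      message(sprintf("epoch %2d  loss %.4f  val AUC %s  val loss %.4f", ep,
                      hist$train_loss[ep],
                      ifelse(is.na(auc), "NA", sprintf("%.3f", auc)), vloss))
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

# Elementwise sum of two parameter-gradient trees.
add_grads <- function(a, b) {
  if (is.list(a)) {
    out <- a
    keys <- names(a) %||% seq_along(a)
    for (k in keys) {
      if (identical(k, "stride") || is.null(a[[k]])) next
      out[[k]] <- add_grads(a[[k]], b[[k]])
    }
    return(out)
  }
  a + b
}

#' Probability heat map of a volume
#'
#' Partitions the Z-map into PoCs, scores each with the model, and writes
#' the score into the voxels of both cube footprints; overlapping
#' contributions are averaged. The map is congruent with the input grid,
#' zero outside the brain mask, and mirror-symmetric by construction (the
#' pair score cannot distinguish the two sides; see
#' [lateralize_focus()]).
#'
#' @param model a trained `siamese_model` (untrained models are refused).
#' @param zmap a [to_zmap()] result.
#' @param n,stride cube size and stride for [partition_pocs()]. The
#'   inference default `stride = n/4` samples the score profile densely
#'   enough to resolve foci smaller than one cube.
#' @param allow_untrained score with an untrained model anyway (used for
#'   null checks).
#' @return a `heatmap` object: list with `data` (array of probabilities),
#'   `mask`, `spacing`, `coverage` (number of cube footprints covering
#'   each voxel) and `baseline` (the model's zero-difference score
#'   `sigmoid(b_head)`).
#' @export
siamese_heatmap <- function(model, zmap, n = model$config$input_n,
                            stride = max(1L, n %/% 4L),
                            allow_untrained = FALSE) {
  if (!model$trained && !allow_untrained) {
    stop("model is untrained; pass allow_untrained = TRUE to score anyway")
  }
  d0 <- dim(zmap$data)
  pocs <- partition_pocs(zmap, n = n, stride = stride)
  p <- score_batch(model$params, pocs)
  nx <- d0[1] + d0[1] %% 2L
  half <- nx %/% 2L
  acc <- array(0, c(nx, d0[2], d0[3]))
  cnt <- array(0, c(nx, d0[2], d0[3]))
  for (k in seq_along(pocs)) {
    pc <- pocs[[k]]
    ix <- pc$origin[1] + seq_len(n) - 1L
    iy <- pc$origin[2] + seq_len(n) - 1L
    iz <- pc$origin[3] + seq_len(n) - 1L
    for (side in c(pc$side, setdiff(c("left", "right"), pc$side))) {
      vx <- if (side == "left") ix else nx + 1L - ix
      acc[vx, iy, iz] <- acc[vx, iy, iz] + p[k]
      cnt[vx, iy, iz] <- cnt[vx, iy, iz] + 1
    }
  }
  map <- array(0, c(nx, d0[2], d0[3]))
  nz <- cnt > 0
  map[nz] <- acc[nz] / cnt[nz]
  map <- map[seq_len(d0[1]), , , drop = FALSE]
  cnt <- cnt[seq_len(d0[1]), , , drop = FALSE]
  map[!zmap$mask] <- 0
  structure(list(data = map, mask = zmap$mask, spacing = zmap$spacing,
                 coverage = cnt,
                 baseline = plogis(model$params$head$b)),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> %s, baseline %.3f, max %.3f\n",
              paste(dim(x$data), collapse = "x"), x$baseline,
              max(x$data[x$mask])))
  invisible(x)
}

#' Localize the focus from a probability heat map
#'
#' Thresholds the heat map (voxels with `p >= threshold`, within the
#' brain mask) and retains connected components. Because the heat map is
#' mirror-symmetric, the default `keep = "bilateral"` retains the largest
#' component together with its mirror twin; `"largest"` keeps one
#' component (ties broken by total heat, then scan order), `"all"` keeps
#' every supra-threshold component.
#'
#' If `threshold` is `NULL`, an adaptive threshold is used:
#' `baseline + response_frac * (max - baseline)`. The default
#' `response_frac = 0.9` keeps only voxels whose covering pairs-of-cubes
#' score near-unanimously abnormal (a voxel's averaged response reaches
#' a fraction close to 1 only when essentially every cube containing it
#' is classified abnormal; the 10% slack tolerates cubes that barely
#' graze the focus). If the map maximum exceeds the baseline by less
#' than `min_response`, no focus is declared and an empty mask is
#' returned. Voxels only partially covered by the cube grid (map edges)
#' inherit single-cube scores and are excluded when the heat map
#' carries a `coverage` field.
#'
#' @param heatmap a [siamese_heatmap()] result.
#' @param threshold absolute probability threshold, or `NULL` (adaptive).
#' @param response_frac fraction of the baseline-to-maximum response for
#'   the adaptive threshold.
#' @param keep `"bilateral"`, `"largest"` or `"all"`.
#' @param min_response minimum map response above baseline for the
#'   adaptive threshold to declare a focus. The default (0.01) only
#'   guards against declaring a focus on a null (near-constant) map; the
#'   trained score scale is compressed near the baseline, so larger
#'   absolute floors are not meaningful.
#' @return logical focus mask, same shape as the map.
#' @export
localize_focus <- function(heatmap, threshold = NULL,
                           keep = c("bilateral", "largest", "all"),
                           response_frac = 0.9, min_response = 0.01) {
  keep <- match.arg(keep)
  map <- heatmap$data
  inb <- heatmap$mask
  if (is.null(threshold)) {
    # adaptive mode additionally excludes partially covered edge voxels
    if (!is.null(heatmap$coverage)) {
      inb <- inb & heatmap$coverage >= max(heatmap$coverage)
    }
    mx <- max(map[inb])
    if (mx < heatmap$baseline + min_response) {
      return(array(FALSE, dim(map)))
    }
    threshold <- heatmap$baseline + response_frac * (mx - heatmap$baseline)
  }
  m <- map >= threshold & inb
  if (!any(m) || keep == "all") return(m)
  lab <- .cc3d_label(m, 26L)
  nlab <- max(lab)
  if (nlab == 1L) return(m)
  sizes <- tabulate(lab[lab > 0L], nlab)
  heat <- vapply(seq_len(nlab), function(l) sum(map[lab == l]), numeric(1))
  cand <- which(sizes == max(sizes))
  main <- cand[which.max(heat[cand])]
  keep_ids <- main
  if (keep == "bilateral") {
    twin <- flip_lr(array(lab == main, dim(map)))
    for (l in setdiff(seq_len(nlab), main)) {
      comp <- lab == l
      if (sum(comp & twin) >= 0.5 * sizes[l]) keep_ids <- c(keep_ids, l)
    }
  }
  array(lab %in% keep_ids, dim(map))
}

#' Normative template from control Z-maps
#'
#' Voxelwise mean of the control subjects' Z-maps; used to lateralize a
#' mirror-symmetric localization.
#'
#' @param zmaps list of `zmap` objects (or a phantom cohort, from which
#'   the controls are taken).
#' @return 3D array.
#' @export
normative_template <- function(zmaps) {
  if (length(zmaps) > 0L && inherits(zmaps[[1]], "phantom_case")) {
    zmaps <- lapply(Filter(function(cs) !any(cs$focus_mask), zmaps),
                    function(cs) to_zmap(cs$volume))
  }
  stopifnot(length(zmaps) >= 1L)
  Reduce(`+`, lapply(zmaps, function(z) z$data)) / length(zmaps)
}

#' Lateralize a (possibly bilateral) focus mask
#'
#' The Siamese pair score is blind to which hemisphere is abnormal, so a
#' thresholded heat map contains the focus and its mirror image. This
#' step keeps the hemisphere part of the mask whose Z-map deviates more
#' (mean absolute difference) from a normative template built from
#' controls.
#'
#' @param mask logical focus mask.
#' @param zmap the subject's `zmap`.
#' @param template a [normative_template()] array.
#' @return unilateral logical mask (empty input returned unchanged).
#' @export
lateralize_focus <- function(mask, zmap, template) {
  if (!any(mask)) return(mask)
  d <- dim(mask)
  half <- d[1] %/% 2L
  leftpart <- mask
  leftpart[(half + 1L):d[1], , ] <- FALSE
  rightpart <- mask & !leftpart
  if (!any(leftpart)) return(rightpart)
  if (!any(rightpart)) return(leftpart)
  dev <- abs(zmap$data - template)
  if (mean(dev[leftpart]) >= mean(dev[rightpart])) leftpart else rightpart
}
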