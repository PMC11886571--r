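#' Training configuration
#'
#' All hyperparameters of the representation-learning objective. Defaults
#' follow the method's stated settings: loss weights \code{lambda1 = 0.2}
#' and \code{lambda2 = 0.02}, learning rate 0.001, 900 epochs, 3 aggregation
#' hops; mask rate 0.5 with K = 3 re-masked decoding views and scaling
#' exponent gamma = 2 are the package defaults for the unstated knobs.
#'
#' @param lambda1 weight of the regularization loss.
#' @param lambda2 weight of the node-discrimination loss.
#' @param learning_rate Adam learning rate.
#' @param epochs number of full-batch epochs.
#' @param mask_rate fraction of nodes feature-masked per epoch; 0 degrades
#'   the task to a plain (unmasked) graph autoencoder reconstructing all
#'   nodes.
#' @param remask_views number of re-masked decoding views K.
#' @param remask_rate latent re-mask fraction; defaults to \code{mask_rate}.
#' @param gamma scaled-cosine-error exponent (>= 1).
#' @param latent_dim latent width d.
#' @param head_dim contrastive head output width d'.
#' @param hops parameter-free propagation steps n for multi-hop fusion.
#' @param reg_stop_gradient if FALSE (default), the regularization
#'   objective is two-sided: gradient flows through both projector
#'   branches, letting the MLP align them rapidly so the regularization
#'   loss decays to near zero early in training. If TRUE the full-graph
#'   projection is treated as a stop-gradient constant target.
#' @param seed integer seed pinning every RNG stream of a run.
#' @param device \code{"cpu"} (kept for config compatibility).
#' @return object of class \code{training_config}.
#' @export
training_config <- function(lambda1 = 0.2, lambda2 = 0.02,
                            learning_rate = 0.001, epochs = 900,
                            mask_rate = 0.5, remask_views = 3,
                            remask_rate = mask_rate, gamma = 2,
                            latent_dim = 64, head_dim = 32, hops = 3,
                            reg_stop_gradient = FALSE,
                            seed = 0, device = "cpu") {
  stopifnot(lambda1 >= 0, lambda2 >= 0, epochs >= 1, gamma >= 1,
            mask_rate >= 0, mask_rate <= 1, remask_views >= 1,
            latent_dim >= 1, head_dim >= 1, hops >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 mask_rate = mask_rate, remask_views = as.integer(remask_views),
                 remask_rate = remask_rate, gamma = gamma,
                 latent_dim = as.integer(latent_dim),
                 head_dim = as.integer(head_dim), hops = as.integer(hops),
                 reg_stop_gradient = isTRUE(reg_stop_gradient),
                 seed = as.integer(seed), device = device),
            class = "training_config")
}

#' Overall training loss
#'
#' \code{L = L_recon + lambda1 * L_reg + lambda2 * L_discri}.
#'
#' @param l_recon,l_reg,l_discri the three loss components (>= 0).
#' @param cfg a \code{\link{training_config}} supplying the weights.
#' @return scalar total loss.
#' @export
total_loss <- function(l_recon, l_reg, l_discri, cfg = training_config()) {
  l_recon + cfg$lambda1 * l_reg + cfg$lambda2 * l_discri
}

# trainable fields per sub-module
.trainable <- list(enc = c("W", "a1", "a2"), dec = c("W", "a1", "a2"),
                   proj = c("W1", "b1", "W2", "b2"),
                   head = c("W1", "b1", "W2", "b2"))

zero_grads <- function(model) {
  g <- list()
  for (mod in names(.trainable))
    for (f in .trainable[[mod]])
      g[[mod]][[f]] <- model[[mod]][[f]] * 0
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_grads <- function(g, mod, upd) {
  for (f in intersect(names(upd), .trainable[[mod]]))
    g[[mod]][[f]] <- g[[mod]][[f]] + upd[[f]]
  g
}

adam_init <- function(model) {
  st <- list(t = 0, m = list(), v = list())
  for (mod in names(.trainable))
    for (f in .trainable[[mod]]) {
      z <- model[[mod]][[f]] * 0
      st$m[[mod]][[f]] <- z
      st$v[[mod]][[f]] <- z
    }
  st
}

adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (mod in names(.trainable))
    for (f in .trainable[[mod]]) {
      g <- grads[[mod]][[f]]
      st$m[[mod]][[f]] <- beta1 * st$m[[mod]][[f]] + (1 - beta1) * g
      st$v[[mod]][[f]] <- beta2 * st$v[[mod]][[f]] + (1 - beta2) * g^2
      mhat <- st$m[[mod]][[f]] / bc1
      vhat <- st$v[[mod]][[f]] / bc2
      model[[mod]][[f]] <- model[[mod]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  list(model = model, state = st)
}

# One full-batch forward/backward pass of the joint objective for a fixed
# masking plan and shuffle permutation. Returns the loss components and the
# analytic gradients of L = L_recon + lambda1*L_reg + lambda2*L_discri with
# respect to every trainable parameter. The regularization branch is
# two-sided unless cfg$reg_stop_gradient makes the projected full-graph
# embedding a constant target; the discrimination branch is skipped when
# lambda2 = 0 (perm may then be NULL), the regularization branch when
# lambda1 = 0.
loss_and_grads <- function(X, edges, model, cfg, plan, perm = NULL) {
  n <- nrow(X)
  use_reg <- cfg$lambda1 > 0
  use_dis <- cfg$lambda2 > 0
  rows <- if (length(plan$masked_nodes)) plan$masked_nodes else seq_len(n)
  grads <- zero_grads(model)

  Xt <- mask_features(X, plan)
  encM <- gat_forward(edges, Xt, model$enc)
  dHm <- matrix(0, n, ncol(encM$out))

  # masked feature reconstruction over K re-masked views
  l_recon <- 0
  for (j in seq_len(plan$remask_views)) {
    Ht <- remask_latent(encM$out, plan, j)
    decj <- gat_forward(edges, Ht, model$dec)
    s <- sce_rows(X, decj$out, rows, cfg$gamma)
    l_recon <- l_recon + s$loss
    bd <- gat_backward(s$dZ / length(rows), decj$cache, model$dec)
    grads <- add_grads(grads, "dec", bd)
    dHt <- bd$dX
    rz <- plan$remask_sets[[j]]
    if (length(rz)) dHt[rz, ] <- 0
    dHm <- dHm + dHt
  }
  l_recon <- l_recon / length(rows)

  l_reg <- 0; l_dis <- 0
  encF <- NULL
  if (use_reg || use_dis) encF <- gat_forward(edges, X, model$enc)

  # regularization against the full-graph target (stop-gradient by
  # default; optionally two-sided)
  dHf <- matrix(0, n, if (!is.null(encF)) ncol(encF$out) else 1)
  if (use_reg) {
    projM <- mlp_forward(encM$out, model$proj)
    projF <- mlp_forward(encF$out, model$proj,
                         keep_cache = !isTRUE(cfg$reg_stop_gradient))
    r <- sce_rows(projF$out, projM$out, seq_len(n), cfg$gamma,
                  grad_x = !isTRUE(cfg$reg_stop_gradient))
    l_reg <- r$loss / n
    bp <- mlp_backward(cfg$lambda1 * r$dZ / n, projM$cache, model$proj)
    grads <- add_grads(grads, "proj", bp)
    dHm <- dHm + bp$dX
    if (!isTRUE(cfg$reg_stop_gradient)) {
      bpx <- mlp_backward(cfg$lambda1 * r$dX / n, projF$cache, model$proj)
      grads <- add_grads(grads, "proj", bpx)
      dHf <- dHf + bpx$dX
    }
  }

  # node discrimination on original vs. feature-shuffled graph
  encP <- NULL; dHp <- NULL
  if (use_dis) {
    encP <- gat_forward(edges, X[perm, , drop = FALSE], model$enc)
    headF <- mlp_forward(encF$out, model$head)
    headP <- mlp_forward(encP$out, model$head)
    dd <- discrimination_forward_backward(headF$out, headP$out)
    l_dis <- dd$loss
    bhF <- mlp_backward(cfg$lambda2 * dd$dZ, headF$cache, model$head)
    bhP <- mlp_backward(cfg$lambda2 * dd$dZ_prime, headP$cache, model$head)
    grads <- add_grads(grads, "head", bhF)
    grads <- add_grads(grads, "head", bhP)
    dHf <- dHf + bhF$dX
    dHp <- bhP$dX
  }

  # encoder backward over the branches that carry gradient
  grads <- add_grads(grads, "enc", gat_backward(dHm, encM$cache, model$enc))
  if (use_dis || (use_reg && !isTRUE(cfg$reg_stop_gradient)))
    grads <- add_grads(grads, "enc", gat_backward(dHf, encF$cache, model$enc))
  if (use_dis)
    grads <- add_grads(grads, "enc", gat_backward(dHp, encP$cache, model$enc))

  list(loss = total_loss(l_recon, l_reg, l_dis, cfg),
       l_recon = l_recon, l_reg = l_reg, l_discri = l_dis, grads = grads)
}

#' Train the self-supervised model on a spatial graph
#'
#' Full-batch optimization of the joint objective: each epoch draws a fresh
#' masking plan and feature permutation, runs the masked-reconstruction
#' branch (encoder -> K re-masked decodings -> scaled cosine error), the
#' regularization branch (projector g aligning the masked-graph and
#' full-graph embeddings), and the node-discrimination branch (shared
#' encoder + head p on
#' original vs. shuffled graph), sums them per the overall loss, and takes
#' one Adam step. All randomness derives from \code{cfg$seed}, so runs are
#' bit-reproducible.
#'
#' @param graph an \code{\link{assemble_graph}} result.
#' @param cfg a \code{\link{training_config}}.
#' @param verbose print progress every \code{verbose} epochs (0 = silent).
#' @return object of class \code{stgmae_fit}: list with the trained
#'   \code{model}, the per-epoch \code{trace} (data.frame with columns
#'   \code{loss, recon, reg, discri}), the final one-hop embedding \code{H}
#'   (encoder applied to the clean graph), and \code{cfg}.
#' @export
train <- function(graph, cfg = training_config(), verbose = 0) {
  set.seed(cfg$seed)
  X <- graph$features
  n <- graph$n_nodes
  edges <- graph$edges
  model <- init_model(ncol(X), cfg$latent_dim, cfg$d_prime %||% cfg$head_dim)
  opt <- adam_init(model)
  tr <- matrix(NA_real_, cfg$epochs, 4,
               dimnames = list(NULL, c("loss", "recon", "reg", "discri")))
  use_dis <- cfg$lambda2 > 0

  for (ep in seq_len(cfg$epochs)) {
    plan <- mask_plan(n, cfg$mask_rate, cfg$remask_views, cfg$remask_rate)
    perm <- if (use_dis) sample.int(n)
    step <- loss_and_grads(X, edges, model, cfg, plan, perm)
    grads <- step$grads
    l_recon <- step$l_recon; l_reg <- step$l_reg; l_dis <- step$l_discri
    l_tot <- step$loss
    if (!is.finite(l_tot)) {
      tr <- as.data.frame(tr[seq_len(ep - 1), , drop = FALSE])
      stop("non-finite loss at epoch ", ep, "; trace:\n",
           paste(utils::capture.output(utils::tail(tr, 5)), collapse = "\n"),
           call. = FALSE)
    }
    tr[ep, ] <- c(l_tot, l_recon, l_reg, l_dis)
    upd <- adam_step(model, grads, opt, cfg$learning_rate)
    model <- upd$model
    opt <- upd$state
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %4d  loss %.4f (recon %.4f reg %.4f discri %.4f)",
                      ep, l_tot, l_recon, l_reg, l_dis))
  }

  H <- encode(graph, graph$features, model$enc)
  structure(list(model = model, trace = as.data.frame(tr), H = H, cfg = cfg),
            class = "stgmae_fit")
}

#' @export
print.stgmae_fit <- function(x, ...) {
  nt <- nrow(x$trace)
  cat("stgmae_fit: ", nt, " epochs; final loss ",
      signif(x$trace$loss[nt], 4), " (recon ", signif(x$trace$recon[nt], 4),
      ", reg ", signif(x$trace$reg[nt], 4), ", discri ",
      signif(x$trace$discri[nt], 4), ")\n", sep = "")
  invisible(x)
}
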