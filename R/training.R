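# Training loops: alignment bootstrap (BasicAlign), joint alignment + MRF
# learning (TrainMRF) and the fixed-alignment baseline (MLM-GREMLIN).
# All gradients are exact reverse-mode: the MRF part is closed-form linear
# algebra, and gradients flow into the encoder through the posterior
# alignment via the dynamic program's Hessian-vector products.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param steps Number of gradient steps.
#' @param batch_size Sequences per step (`NULL` = full batch).
#' @param temperature Alignment temperature during training.
#' @param seed Integer seed driving every random choice (initialization,
#'   masks, mini-batches); equal seeds give identical trajectories.
#' @param mask_rate Masked-language-modelling mask rate.
#' @param lambda_v,lambda_w MRF regularization weights.
#' @param filters,window_half_width Encoder size.
#' @param open,extend Affine gap penalties used by the learned aligner.
#' @param align_mode,restrict_turns Alignment conventions during training.
#' @param encoder_learning_rate Adam rate for the encoder (defaults to
#'   `learning_rate / 10`; the MRF tolerates a much larger step than the
#'   convolutions feeding the aligner).
#' @param init_gain Encoder initialization gain (see [init_encoder()]).
#' @param coverage_weight Weight of the gap-mass coverage term added to the
#'   purity loss during the alignment bootstrap (see [run_basic_align()]).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.01, steps = 100L,
                         batch_size = NULL, temperature = 1.0, seed = 0L,
                         mask_rate = 0.15, lambda_v = 0.01, lambda_w = 0.001,
                         filters = 64L, window_half_width = 5L,
                         open = -3, extend = -0.3,
                         align_mode = "global", restrict_turns = TRUE,
                         encoder_learning_rate = NULL, init_gain = 2,
                         coverage_weight = 4) {
  if (learning_rate <= 0 || steps < 1 || temperature <= 0) {
    stop("learning_rate, steps and temperature must be positive",
         call. = FALSE)
  }
  if (mask_rate <= 0 || mask_rate >= 1) {
    stop("`mask_rate` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(encoder_learning_rate)) {
    encoder_learning_rate <- learning_rate / 10
  }
  structure(list(learning_rate = learning_rate, steps = as.integer(steps),
                 batch_size = batch_size, temperature = temperature,
                 seed = as.integer(seed), mask_rate = mask_rate,
                 lambda_v = lambda_v, lambda_w = lambda_w,
                 filters = as.integer(filters),
                 window_half_width = as.integer(window_half_width),
                 open = open, extend = extend, align_mode = align_mode,
                 restrict_turns = isTRUE(restrict_turns),
                 encoder_learning_rate = encoder_learning_rate,
                 init_gain = init_gain, coverage_weight = coverage_weight),
            class = "train_config")
}

cfg_align_params <- function(cfg) {
  align_params(temperature = cfg$temperature, gap_mode = "affine",
               open = cfg$open, extend = cfg$extend,
               align_mode = cfg$align_mode,
               restrict_turns = cfg$restrict_turns)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

# ---- shared LAM forward/backward -----------------------------------------

# forward: one-hot sequences -> posteriors + profiles; keeps every
# intermediate needed for the backward pass
lam_forward <- function(Xq, Xs, enc, ap) {
  Eq <- encode(Xq, enc)
  B <- length(Xs)
  Es <- vector("list", B)
  as_ <- vector("list", B)
  for (k in seq_len(B)) {
    Es[[k]] <- encode(Xs[[k]], enc)
    as_[[k]] <- tcrossprod(Eq, Es[[k]])
  }
  post <- cpp_sw_posterior_batch(as_, ap$temperature, ap$open, ap$extend,
                                 ap$align_mode == "local", ap$restrict_turns)
  L <- nrow(Xq)
  A <- ncol(Xq)
  profiles <- array(0, c(B, L, A))
  gap <- matrix(0, B, L)
  P <- vector("list", B)
  for (k in seq_len(B)) {
    P[[k]] <- post[[k]]$posterior
    pk <- P[[k]] %*% Xs[[k]]
    profiles[k, , ] <- pk
    gap[k, ] <- 1 - rowSums(pk)
  }
  list(Eq = Eq, Es = Es, a = as_, P = P, profiles = profiles, gap = gap)
}

# backward: given dL/dprofiles (B x L x A array), push gradients through
# the profile contraction, the posterior (Hessian-vector product), the
# similarity dot products and the convolution
lam_backward <- function(fw, gprofiles, Xq, Xs, enc, ap) {
  B <- length(Xs)
  us <- vector("list", B)
  for (k in seq_len(B)) {
    gpk <- matrix(gprofiles[k, , ], dim(gprofiles)[2], dim(gprofiles)[3])
    us[[k]] <- gpk %*% t(Xs[[k]]) # dL/dP_k
  }
  vjp <- cpp_sw_vjp_batch(fw$a, us, ap$temperature, ap$open, ap$extend,
                          ap$align_mode == "local", ap$restrict_turns)
  dEq <- fw$Eq * 0
  dkernel <- enc$kernel * 0
  dbias <- enc$bias * 0
  w <- enc$window_half_width
  for (k in seq_len(B)) {
    abar <- vjp[[k]]$abar
    dEq <- dEq + abar %*% fw$Es[[k]]
    dEk <- crossprod(abar, fw$Eq)
    gk <- encode_backward(Xs[[k]], w, dEk)
    dkernel <- dkernel + gk$kernel
    dbias <- dbias + gk$bias
  }
  gq <- encode_backward(Xq, w, dEq)
  list(kernel = dkernel + gq$kernel, bias = dbias + gq$bias)
}

# note: gap mass is 1 - rowSums(profile), so a loss written in terms of
# profiles and gap must fold the gap dependence into gprofiles before
# calling lam_backward (the mlm gradient already does this).

#' Alignment bootstrap loss
#'
#' The column-agreement objective of the alignment bootstrap phase: build
#' the soft MSA implied by the current encoder and sum, over sequences and
#' query columns, the squared difference between each sequence's profile
#' row and the column's average profile.  The loss is low when every
#' column is dominated by one or a few residues, i.e. when the sequences
#' are aligned consistently.
#'
#' @param seqs List of sequences (strings or one-hot matrices).
#' @param query Query sequence.
#' @param enc An [encoder_params()] object.
#' @param params An [align_params()] object.
#' @return Scalar loss.
#' @export
basic_align_loss <- function(seqs, query, enc, params) {
  if (length(seqs) < 2L) {
    stop("alignment bootstrap needs at least 2 sequences", call. = FALSE)
  }
  Xq <- onehot_of(query, enc)
  Xs <- lapply(seqs, onehot_of, enc = enc)
  fw <- lam_forward(Xq, Xs, enc, as_align_params(params))
  basic_align_loss_value(fw$profiles)
}

basic_align_loss_value <- function(profiles) {
  colmean <- apply(profiles, c(2, 3), mean)
  dev <- sweep(profiles, c(2, 3), colmean)
  sum(dev^2)
}

# gradient: because the column mean is the minimizer of the sum of squares,
# the mean's own dependence cancels and dL/dprofile_k = 2 * (p_k - mean)
basic_align_grad <- function(profiles) {
  colmean <- apply(profiles, c(2, 3), mean)
  2 * sweep(profiles, c(2, 3), colmean)
}

#' Alignment bootstrap training (BasicAlign)
#'
#' Learns encoder convolutions from scratch by gradient descent on the
#' column-purity objective of [basic_align_loss()]: starting from a seeded
#' random encoder, the learned similarity scores are adjusted so that the
#' soft MSA's columns become residue-pure.  This yields a sensible
#' alignment before any pairwise model is introduced, and its encoder is
#' the usual initialization for [run_train_mrf()].
#'
#' The descended objective is the purity loss plus
#' `coverage_weight * sum(gap mass)`.  The coverage term removes the purity
#' loss's degenerate minimum (aligning nothing makes every profile row
#' equal the column mean trivially); with it, the bootstrap keeps the
#' family aligned while sorting residues into consistent columns.  The
#' phase is an initializer and is meant to run for a modest number of
#' steps: the purity objective on its own eventually distorts a correct
#' alignment (for instance by merging same-residue columns), and the
#' masked-language-modelling phase is what anchors and refines the final
#' alignment.
#'
#' @param seqs List of unaligned sequences; `query` the reference.
#' @param query Query sequence (kept uncorrupted, defines the columns).
#' @param cfg A [train_config()].
#' @param enc_init Optional starting encoder (default: seeded random).
#' @return A list of class `basic_align_fit` with `encoder`, `log` (data
#'   frame of step/loss) and `align_params`.
#' @export
run_basic_align <- function(seqs, query, cfg, enc_init = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(seqs) < 2L) {
    stop("alignment bootstrap needs at least 2 sequences", call. = FALSE)
  }
  ap <- cfg_align_params(cfg)
  alphabet <- guess_alphabet(query, seqs)
  if (is.null(enc_init)) {
    enc_init <- init_encoder(cfg$window_half_width, cfg$filters, alphabet,
                             seed = cfg$seed, gain = cfg$init_gain)
  }
  enc <- enc_init
  Xq <- onehot_of(query, enc)
  Xs <- lapply(seqs, onehot_of, enc = enc)
  set.seed(cfg$seed + 1L)
  pars <- list(kernel = enc$kernel, bias = enc$bias)
  st <- adam_init(pars)
  log <- data.frame(step = integer(0), loss = numeric(0),
                    purity = numeric(0), gap_mass = numeric(0))
  B <- length(Xs)
  for (step in seq_len(cfg$steps)) {
    idx <- pick_batch(B, cfg$batch_size)
    fw <- lam_forward(Xq, Xs[idx], enc, ap)
    purity <- basic_align_loss_value(fw$profiles)
    gap_total <- sum(fw$gap)
    loss <- purity + cfg$coverage_weight * gap_total
    if (!is.finite(loss)) {
      stop("alignment bootstrap diverged (loss is not finite); ",
           "try a lower learning rate", call. = FALSE)
    }
    gp <- basic_align_grad(fw$profiles) - cfg$coverage_weight
    g <- lam_backward(fw, gp, Xq, Xs[idx], enc, ap)
    upd <- adam_step(st, pars, g, cfg$learning_rate)
    st <- upd$state
    pars <- upd$params
    enc$kernel <- pars$kernel
    enc$bias <- pars$bias
    log <- rbind(log, data.frame(step = step, loss = loss, purity = purity,
                                 gap_mass = gap_total))
  }
  structure(list(encoder = enc, log = log, align_params = ap),
            class = "basic_align_fit")
}

pick_batch <- function(B, batch_size) {
  if (is.null(batch_size) || batch_size >= B) seq_len(B)
  else sort(sample.int(B, batch_size))
}

guess_alphabet <- function(query, seqs) {
  chars <- unique(unlist(lapply(c(list(query), seqs), function(s) {
    if (is.matrix(s)) rownames(s) else seq_chars(s)
  })))
  if (all(chars %in% c("A", "C", "G", "U", "N"))) "rna" else "protein"
}

#' Joint alignment + MRF training (TrainMRF)
#'
#' The second training phase: a masked-language-modelling objective on the
#' soft MSA is descended jointly in the MRF parameters and (unless frozen)
#' the encoder convolutions, so the network can adjust the alignment while
#' learning the pairwise model.  With `freeze_encoder = TRUE` and
#' `profiles` supplied, the loop reduces exactly to the fixed-alignment
#' baseline [run_mlm_gremlin()] (identical loss trajectories under equal
#' seeds).
#'
#' @inheritParams run_basic_align
#' @param enc_init Starting encoder, typically `run_basic_align(...)$encoder`.
#' @param freeze_encoder If TRUE only the MRF is trained.
#' @param profiles Optional fixed [soft_msa()] to use instead of the
#'   encoder-derived soft MSA (implies a frozen encoder).
#' @return A list of class `smurf_model` with `encoder`, `mrf`
#'   ([mrf_params()]), `align_params`, `log` and `config`.
#' @export
run_train_mrf <- function(seqs, query, enc_init, cfg, freeze_encoder = FALSE,
                          profiles = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  ap <- cfg_align_params(cfg)
  enc <- enc_init
  fixed <- !is.null(profiles)
  if (fixed) freeze_encoder <- TRUE
  Xq <- onehot_of(query, enc)
  Xs <- lapply(seqs, onehot_of, enc = enc)
  L <- nrow(Xq)
  A <- ncol(Xq)
  B <- length(Xs)
  if (fixed) {
    pr <- as_profiles(profiles)
    if (!all(dim(pr$p) == c(B, L, A))) {
      stop("fixed profiles do not match the sequence set", call. = FALSE)
    }
  }
  core <- mrf_train_core(
    B = B, L = L, A = A, cfg = cfg,
    get_profiles = function(idx) {
      if (fixed) {
        list(p = pr$p[idx, , , drop = FALSE],
             gap = pr$gap[idx, , drop = FALSE], fw = NULL)
      } else {
        fw <- lam_forward(Xq, Xs[idx], enc, ap)
        list(p = fw$profiles, gap = fw$gap, fw = fw)
      }
    },
    encoder_grad = if (freeze_encoder) NULL else function(fw, gprofiles, idx) {
      lam_backward(fw, gprofiles, Xq, Xs[idx], enc, ap)
    },
    set_encoder = function(kernel, bias) {
      enc$kernel <<- kernel
      enc$bias <<- bias
    },
    enc = enc
  )
  structure(list(encoder = enc, mrf = core$mrf, align_params = ap,
                 log = core$log, config = cfg),
            class = "smurf_model")
}

#' Fixed-alignment baseline (MLM-GREMLIN)
#'
#' Trains the MRF alone, with the same masked-language-modelling loop as
#' [run_train_mrf()], on hard one-hot profiles derived from a fixed
#' alignment in query coordinates (A3M insertion states are discarded; gap
#' characters carry full gap mass).
#'
#' @param msa An `a3m` object, a character matrix of aligned rows, or a
#'   [soft_msa()].  The first row is the query.
#' @param cfg A [train_config()].
#' @param alphabet Alphabet for character input.
#' @param include_query Whether the first row participates as a training
#'   sequence (default TRUE).
#' @return An [mrf_params()] object with the training log as attribute
#'   `"log"`.
#' @export
run_mlm_gremlin <- function(msa, cfg, alphabet = "protein",
                            include_query = TRUE) {
  stopifnot(inherits(cfg, "train_config"))
  pr <- as_profiles(msa_profiles(msa, alphabet, include_query))
  B <- dim(pr$p)[1]
  L <- dim(pr$p)[2]
  A <- dim(pr$p)[3]
  core <- mrf_train_core(
    B = B, L = L, A = A, cfg = cfg,
    get_profiles = function(idx) {
      list(p = pr$p[idx, , , drop = FALSE],
           gap = pr$gap[idx, , drop = FALSE], fw = NULL)
    },
    encoder_grad = NULL, set_encoder = NULL, enc = NULL
  )
  structure(core$mrf, log = core$log)
}

# convert a fixed MSA (a3m rows / character matrix / soft_msa) to hard
# one-hot profiles in query coordinates
msa_profiles <- function(msa, alphabet = "protein", include_query = TRUE) {
  if (inherits(msa, "soft_msa")) return(msa)
  alphabet <- as_alphabet(alphabet)
  mat <- if (is.matrix(msa)) msa else a3m_to_matrix(msa)
  if (!include_query) mat <- mat[-1, , drop = FALSE]
  if (any(nchar(mat) != 1L)) {
    stop("ragged MSA: every cell must be a single character", call. = FALSE)
  }
  B <- nrow(mat)
  L <- ncol(mat)
  A <- alphabet$size
  profiles <- array(0, c(B, L, A))
  for (k in seq_len(B)) {
    idx <- match(toupper(mat[k, ]), alphabet$letters)
    hit <- which(!is.na(idx))
    profiles[cbind(k, hit, idx[hit])] <- 1
  }
  gap <- 1 - apply(profiles, c(1, 2), sum)
  structure(list(profiles = profiles, gap_mass = gap, alphabet = alphabet),
            class = "soft_msa")
}

# the shared training loop: everything that is identical between TrainMRF
# and MLM-GREMLIN lives here so that their trajectories coincide exactly
# when the profiles do
mrf_train_core <- function(B, L, A, cfg, get_profiles, encoder_grad,
                           set_encoder, enc) {
  fields <- matrix(0, L, A)
  Wraw <- matrix(0, L * A, L * A)
  mrf_pars <- list(fields = fields, Wraw = Wraw)
  mrf_st <- adam_init(mrf_pars)
  learn_enc <- !is.null(encoder_grad)
  if (learn_enc) {
    enc_pars <- list(kernel = enc$kernel, bias = enc$bias)
    enc_st <- adam_init(enc_pars)
  }
  set.seed(cfg$seed + 2L)
  log <- data.frame(step = integer(0), loss = numeric(0))
  for (step in seq_len(cfg$steps)) {
    idx <- pick_batch(B, cfg$batch_size)
    mask <- draw_mask(length(idx), L, cfg$mask_rate)
    prof <- get_profiles(idx)
    W <- sym_couplings(mrf_pars$Wraw, L, A)
    g <- mlm_loss_grad(prof$p, prof$gap, mask, mrf_pars$fields, W,
                       cfg$lambda_v, cfg$lambda_w)
    if (!is.finite(g$loss)) {
      stop("MRF training diverged (loss is not finite); ",
           "try a lower learning rate", call. = FALSE)
    }
    upd <- adam_step(mrf_st, mrf_pars,
                     list(fields = g$gfields, Wraw = g$gW),
                     cfg$learning_rate)
    mrf_st <- upd$state
    mrf_pars <- upd$params
    if (learn_enc) {
      ge <- encoder_grad(prof$fw, g$gprofiles, idx)
      upe <- adam_step(enc_st, enc_pars, ge, cfg$encoder_learning_rate)
      enc_st <- upe$state
      enc_pars <- upe$params
      set_encoder(enc_pars$kernel, enc_pars$bias)
    }
    log <- rbind(log, data.frame(step = step, loss = g$loss))
  }
  mrf <- mrf_params(mrf_pars$fields, sym_couplings(mrf_pars$Wraw, L, A))
  list(mrf = mrf, log = log)
}

#' @export
print.smurf_model <- function(x, ...) {
  cat(sprintf("<smurf_model> encoder: window %d, %d filters\n",
              2L * x$encoder$window_half_width + 1L, x$encoder$filters))
  cat(sprintf("  MRF: L = %d, A = %d; trained %d steps, final loss %.4f\n",
              x$mrf$L, x$mrf$A, nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @export
print.basic_align_fit <- function(x, ...) {
  cat(sprintf("<basic_align_fit> %d steps, loss %.4f -> %.4f\n",
              nrow(x$log), x$log$loss[1], x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' Save / load a trained model
#'
#' Checkpoints are RDS files holding a versioned list with the encoder,
#' MRF, alignment parameters and training configuration.
#'
#' @param model A `smurf_model`.
#' @param path File path.
#' @export
write_smurf_model <- function(model, path) {
  stopifnot(inherits(model, "smurf_model"))
  saveRDS(list(format = "smurf_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_smurf_model
#' @export
read_smurf_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "smurf_model")) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  x$model
}
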