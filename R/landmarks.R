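#' Configuration for multi-scale landmark navigation agents
#'
#' One Q-learning agent per spatial resolution learns to navigate a volume
#' toward a target landmark with six unit-voxel moves. The state is the
#' normalized intensity patch around the agent; the per-step reward is the
#' decrease in Euclidean distance (mm) to the target, with a terminal bonus
#' when the agent lands within one voxel. Detection runs the agents coarse
#' to fine, so the coarse agent supplies the capture range and the fine
#' agent the precision.
#'
#' @param resolutions_mm strictly descending resolutions (mm), coarse first.
#' @param patch_vox cubic state patch edge (voxels, odd).
#' @param max_steps episode step limit.
#' @param episodes training episodes per resolution.
#' @param epsilon_start,epsilon_end linear epsilon-greedy schedule.
#' @param replay_capacity experience replay size.
#' @param discount Q-learning discount factor.
#' @param batch_size minibatch size per update.
#' @param learning_rate Adam learning rate for the Q-network.
#' @param hidden hidden units of the Q-network MLP.
#' @param target_update steps between target-network refreshes.
#' @param seed integer seed.
#' @return An `aq_agent_config` list.
#' @export
agent_config <- function(resolutions_mm = c(16, 8, 4), patch_vox = 9,
                         max_steps = 80, episodes = 300,
                         epsilon_start = 1, epsilon_end = 0.1,
                         replay_capacity = 1e4, discount = 0.9,
                         batch_size = 32, learning_rate = 1e-3, hidden = 64,
                         target_update = 200, seed = 1L) {
  stopifnot(all(diff(resolutions_mm) < 0), episodes >= 1,
            patch_vox %% 2 == 1)
  structure(list(resolutions_mm = resolutions_mm, patch_vox = patch_vox,
                 max_steps = max_steps, episodes = episodes,
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 replay_capacity = replay_capacity, discount = discount,
                 batch_size = batch_size, learning_rate = learning_rate,
                 hidden = hidden, target_update = target_update,
                 seed = as.integer(seed)), class = "aq_agent_config")
}

.actions6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))

# Normalized intensity patch (vector) around integer voxel pos (0-based).
.state_patch <- function(arr, d, pos, psz) {
  half <- psz %/% 2
  out <- array(-50, rep(psz, 3))
  lo <- pos - half; hi <- pos + half          # 0-based inclusive
  slo <- pmax(lo, 0); shi <- pmin(hi, d - 1L)
  if (all(slo <= shi)) {
    out[(slo[1] - lo[1] + 1):(shi[1] - lo[1] + 1),
        (slo[2] - lo[2] + 1):(shi[2] - lo[2] + 1),
        (slo[3] - lo[3] + 1):(shi[3] - lo[3] + 1)] <-
      arr[(slo[1] + 1):(shi[1] + 1), (slo[2] + 1):(shi[2] + 1),
          (slo[3] + 1):(shi[3] + 1)]
  }
  .unet_norm(as.numeric(out))
}

.qnet_init <- function(nin, nh) {
  list(W1 = matrix(rnorm(nin * nh, 0, sqrt(2 / nin)), nin, nh),
       b1 = numeric(nh),
       W2 = matrix(rnorm(nh * 6, 0, sqrt(2 / nh)), nh, 6),
       b2 = numeric(6))
}

.qnet_fwd <- function(net, S) {
  H <- S %*% net$W1
  H <- sweep(H, 2, net$b1, "+")
  H[H < 0] <- 0
  Q <- sweep(H %*% net$W2, 2, net$b2, "+")
  list(H = H, Q = Q)
}

#' Train navigation agents for one landmark
#'
#' @param cases list of `list(volume, truth)` phantom cases with ground-truth
#'   landmark positions.
#' @param landmark_id one of the five landmark names (e.g.
#'   `"brachiocephalic"`).
#' @param cfg an [agent_config()].
#' @param verbose print per-resolution progress.
#' @return An `aq_landmark_agents` object: one Q-network per resolution plus
#'   a training log (mean episode reward and terminal-hit fraction per
#'   resolution).
#' @export
train_landmark_agents <- function(cases, landmark_id,
                                  cfg = agent_config(), verbose = FALSE) {
  for (cs in cases)
    if (is.null(cs$truth$landmarks[[landmark_id]]))
      stop("landmark '", landmark_id, "' missing from a training case")
  set.seed(cfg$seed)
  psz <- cfg$patch_vox
  nin <- psz^3
  agents <- list()
  log <- list()
  for (res in cfg$resolutions_mm) {
    vols <- lapply(cases, function(cs) resample_isotropic(cs$volume, res))
    arrs <- lapply(vols, `[[`, "voxels")
    targets <- lapply(seq_along(cases), function(i)
      as.numeric(world_to_index(vols[[i]],
                                cases[[i]]$truth$landmarks[[landmark_id]])))
    net <- .qnet_init(nin, cfg$hidden)
    tgt_net <- net
    ad <- lapply(c("W1", "b1", "W2", "b2"), function(nm)
      list(m = 0 * net[[nm]], v = 0 * net[[nm]], t = 0))
    names(ad) <- c("W1", "b1", "W2", "b2")
    N <- cfg$replay_capacity
    S <- matrix(0, N, nin); S2 <- matrix(0, N, nin)
    A <- integer(N); Rw <- numeric(N); Dn <- logical(N)
    nbuf <- 0L; wpos <- 0L; gstep <- 0L
    ep_reward <- numeric(cfg$episodes); ep_hit <- logical(cfg$episodes)
    for (ep in seq_len(cfg$episodes)) {
      eps <- cfg$epsilon_start + (cfg$epsilon_end - cfg$epsilon_start) *
        (ep - 1) / max(1, cfg$episodes - 1)
      ci <- sample.int(length(cases), 1)
      arr <- arrs[[ci]]; d <- dim(arr); tg <- targets[[ci]]
      # curriculum: half the episodes start in the capture range around the
      # target so the near-target policy (what coarse-to-fine hand-off
      # exercises) gets dense experience
      pos <- if (runif(1) < 0.5) {
        c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1)) - 1L
      } else {
        as.integer(round(tg + sample(-4:4, 3, replace = TRUE)))
      }
      pos <- pmin(pmax(pos, 0L), d - 1L)
      st <- .state_patch(arr, d, pos, psz)
      total <- 0
      for (step in seq_len(cfg$max_steps)) {
        a <- if (runif(1) < eps) sample.int(6, 1) else
          which.max(.qnet_fwd(net, matrix(st, 1))$Q)
        pos2 <- pmin(pmax(pos + .actions6[a, ], 0L), d - 1L)
        dist1 <- sqrt(sum((pos - tg)^2)) * res
        dist2 <- sqrt(sum((pos2 - tg)^2)) * res
        done <- dist2 <= res
        rew <- dist1 - dist2 + if (done) 2 * res else 0
        st2 <- .state_patch(arr, d, pos2, psz)
        wpos <- (wpos %% N) + 1L
        nbuf <- min(nbuf + 1L, N)
        S[wpos, ] <- st; S2[wpos, ] <- st2
        A[wpos] <- a; Rw[wpos] <- rew; Dn[wpos] <- done
        total <- total + rew
        pos <- pos2; st <- st2
        gstep <- gstep + 1L
        if (nbuf >= cfg$batch_size) {
          bi <- sample.int(nbuf, cfg$batch_size)
          # double-DQN target: online net picks the action, target net rates it
          q2o <- .qnet_fwd(net, S2[bi, , drop = FALSE])$Q
          a2 <- max.col(q2o, ties.method = "first")
          q2t <- .qnet_fwd(tgt_net, S2[bi, , drop = FALSE])$Q
          yb <- Rw[bi] + cfg$discount * (!Dn[bi]) *
            q2t[cbind(seq_len(cfg$batch_size), a2)]
          fw <- .qnet_fwd(net, S[bi, , drop = FALSE])
          G <- matrix(0, cfg$batch_size, 6)
          sel <- cbind(seq_len(cfg$batch_size), A[bi])
          # Huber (delta = 1) gradient on the taken action
          resid <- fw$Q[sel] - yb
          G[sel] <- pmin(pmax(resid, -1), 1) / cfg$batch_size
          gW2 <- t(fw$H) %*% G
          gb2 <- colSums(G)
          dH <- G %*% t(net$W2)
          dH[fw$H <= 0] <- 0
          gW1 <- t(S[bi, , drop = FALSE]) %*% dH
          gb1 <- colSums(dH)
          gr <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
          for (nm in names(gr)) {
            up <- .adam_step(net[[nm]], gr[[nm]], ad[[nm]],
                             cfg$learning_rate)
            net[[nm]] <- up$par; ad[[nm]] <- up$st
          }
          if (gstep %% cfg$target_update == 0L) tgt_net <- net
        }
        if (done) break
      }
      ep_reward[ep] <- total
      ep_hit[ep] <- done
    }
    key <- paste0("res", res)
    agents[[key]] <- list(net = net, res = res)
    log[[key]] <- list(mean_reward = mean(ep_reward),
                       hit_rate = mean(ep_hit),
                       late_hit_rate = mean(tail(ep_hit, 50)))
    if (verbose)
      message(sprintf("res %g mm: hit rate %.2f (last 50: %.2f)", res,
                      mean(ep_hit), mean(tail(ep_hit, 50))))
  }
  structure(list(agents = agents, cfg = cfg, landmark_id = landmark_id,
                 log = log), class = "aq_landmark_agents")
}

#' @export
print.aq_landmark_agents <- function(x, ...) {
  cat(sprintf("<aq_landmark_agents> landmark '%s', resolutions %s mm\n",
              x$landmark_id,
              paste(x$cfg$resolutions_mm, collapse = "/")))
  for (nm in names(x$log))
    cat(sprintf("  %s: training hit rate %.2f\n", nm, x$log[[nm]]$hit_rate))
  invisible(x)
}

# Greedy rollout; returns continuous 0-based index position. Terminates on a
# 2-cycle oscillation (midpoint returned, giving half-voxel precision) or on
# the step limit (flagged).
.greedy_rollout <- function(net, arr, d, pos, psz, max_steps = 200) {
  prev <- NULL
  for (step in seq_len(max_steps)) {
    st <- .state_patch(arr, d, pos, psz)
    a <- which.max(.qnet_fwd(net, matrix(st, 1))$Q)
    pos2 <- pmin(pmax(pos + .actions6[a, ], 0L), d - 1L)
    if (!is.null(prev) && all(pos2 == prev))
      return(list(pos = (pos + pos2) / 2, converged = TRUE))
    if (all(pos2 == pos)) return(list(pos = pos, converged = TRUE))
    prev <- pos
    pos <- pos2
  }
  list(pos = pos, converged = FALSE)
}

#' Detect a landmark with trained multi-scale agents
#'
#' The coarsest agent is launched from `starts` random positions; each finer
#' agent is launched from `starts` positions jittered around the previous
#' estimate. At every scale the terminal positions are aggregated by
#' geometric median, which discards stray rollouts. With a named list of
#' agent sets, all landmarks are detected into one landmark set.
#'
#' @param agents an `aq_landmark_agents`, or a named list of them.
#' @param v an `aq_volume`.
#' @param starts number of rollout starting positions per scale.
#' @param seed seed for the starting positions.
#' @return A named list of 3D world points (mm) with a `low_confidence`
#'   attribute naming landmarks whose rollouts all hit the step limit at
#'   some scale.
#' @export
detect_landmarks <- function(agents, v, starts = 5, seed = 1L) {
  if (inherits(agents, "aq_landmark_agents"))
    agents <- stats::setNames(list(agents), agents$landmark_id)
  out <- list()
  lowconf <- character(0)
  set.seed(seed)
  for (nm in names(agents)) {
    ag <- agents[[nm]]
    psz <- ag$cfg$patch_vox
    est <- NULL
    for (li in seq_along(ag$agents)) {
      a <- ag$agents[[li]]
      w <- resample_isotropic(v, a$res)
      arr <- w$voxels; d <- dim(arr)
      terms <- matrix(0, starts, 3)
      conv <- logical(starts)
      for (t in seq_len(starts)) {
        pos <- if (is.null(est)) {
          c(sample.int(d[1], 1), sample.int(d[2], 1),
            sample.int(d[3], 1)) - 1L
        } else {
          p0 <- as.integer(round(world_to_index(w, est)))
          if (t == 1) p0 else p0 + sample(-2:2, 3, replace = TRUE)
        }
        pos <- pmin(pmax(pos, 0L), d - 1L)
        ro <- .greedy_rollout(a$net, arr, d, pos, psz)
        terms[t, ] <- index_to_world(w, rbind(ro$pos))
        conv[t] <- ro$converged
      }
      est <- geometric_median(terms)
      if (!any(conv)) lowconf <- c(lowconf, nm)
    }
    out[[nm]] <- as.numeric(est)
  }
  attr(out, "low_confidence") <- unique(lowconf)
  out
}

#' Geometric median of points (Weiszfeld iteration)
#'
#' @param pts n x 3 matrix.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return The point minimizing the sum of Euclidean distances.
#' @export
geometric_median <- function(pts, tol = 1e-6, max_iter = 200) {
  pts <- rbind(pts)
  x <- colMeans(pts)
  for (it in seq_len(max_iter)) {
    dd <- sqrt(rowSums(sweep(pts, 2, x)^2))
    if (any(dd < 1e-12)) return(pts[which.min(dd), ])
    w <- 1 / dd
    xn <- colSums(pts * w) / sum(w)
    if (sqrt(sum((xn - x)^2)) < tol) return(xn)
    x <- xn
  }
  x
}

#' Per-landmark Euclidean localization error
#'
#' @param pred,truth named lists of 3D points (mm).
#' @return List with `per_landmark` (named mm vector over shared keys) and
#'   `mean` (unweighted mean mm).
#' @export
landmark_error <- function(pred, truth) {
  keys <- intersect(names(pred), names(truth))
  if (!length(keys)) stop("no shared landmark names")
  per <- vapply(keys, function(k)
    sqrt(sum((as.numeric(pred[[k]]) - as.numeric(truth[[k]]))^2)),
    numeric(1))
  list(per_landmark = per, mean = mean(per))
}

#' Ground-truth landmark provider
#'
#' Pass-through provider used to exercise the geometry and diameter stages
#' independently of detector convergence.
#'
#' @param truth an `aq_ground_truth`.
#' @return The named list of ground-truth landmark points (mm).
#' @export
oracle_landmarks <- function(truth) truth$landmarks

#' Mask-topology landmark provider
#'
#' Derives the five landmarks from a segmentation mask alone, assuming the
#' candy-cane orientation of the phantom (both limb ends caudal, ascending
#' limb at smaller x): the root and celiac points are the centroids of the
#' two tube ends on the lowest mask slices; a centerline between them is
#' extracted and the brachiocephalic / left-common-carotid / left-subclavian
#' points are anchored where the tangent enters, crosses and leaves the arch
#' (tangent-to-vertical angle thresholds at 45 degrees).
#'
#' @param m an `aq_mask`.
#' @param step_mm centerline sampling step (mm).
#' @return Named list of landmark points (mm).
#' @export
landmarks_from_mask <- function(m, step_mm = 2) {
  d <- dim(m$voxels)
  idx <- which(m$voxels, arr.ind = TRUE)
  zmin <- min(idx[, 3])
  base <- idx[idx[, 3] <= zmin + 1, , drop = FALSE]
  xs <- base[, 1]
  split_x <- mean(range(xs))
  left <- base[xs <= split_x, , drop = FALSE]
  right <- base[xs > split_x, , drop = FALSE]
  if (!nrow(left) || !nrow(right))
    stop("mask does not expose two caudal tube ends")
  root <- as.numeric(index_to_world(m, rbind(colMeans(left) - 1)))
  cel <- as.numeric(index_to_world(m, rbind(colMeans(right) - 1)))
  cl <- extract_centerline(m, root, cel, step_mm = step_mm)
  uz <- cl$tangent[, 3]
  n <- length(uz)
  i_bca <- which(uz < cos(pi / 4))[1]
  desc <- which(uz < -cos(pi / 4))
  i_lsa <- desc[desc > i_bca][1]
  if (is.na(i_bca) || is.na(i_lsa))
    stop("could not locate the arch from the mask topology")
  arch <- i_bca:i_lsa
  i_lcc <- arch[which.min(abs(uz[arch]))]
  list(aortic_root = cl$points[1, ],
       brachiocephalic = cl$points[i_bca, ],
       left_common_carotid = cl$points[i_lcc, ],
       left_subclavian = cl$points[i_lsa, ],
       celiac = cl$points[n, ])
}
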