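# Recursive-partition internals shared by the soft-split tree, the weighted
# forest, the boosting machines and the surrogate explainer. Nodes are
# nested lists: internal nodes carry (feature, theta, beta, left, right),
# leaves carry the weighted class distribution (classification) or weighted
# mean (regression).

best_split <- function(x, y, w, type, min_leaf, mtry) {
  n <- length(y); d <- ncol(x)
  feats <- if (is.finite(mtry) && mtry < d) sample.int(d, mtry) else seq_len(d)
  best <- list(score = Inf, feature = NA_integer_, theta = NA_real_)
  for (j in feats) {
    ord <- order(x[, j])
    v <- x[ord, j]; yo <- y[ord]; wo <- w[ord]
    cumW <- cumsum(wo); W <- cumW[n]
    pos <- seq_len(n - 1L)
    ok <- pos >= min_leaf & pos <= n - min_leaf & v[pos] < v[pos + 1L]
    if (!any(ok)) next
    if (type == "class") {
      cumP <- cumsum(wo * yo); P <- cumP[n]
      WL <- cumW[pos]; PL <- cumP[pos]
      WR <- W - WL; PR <- P - PL
      score <- 2 * (PL * (WL - PL) / WL + PR * (WR - PR) / WR)
    } else {
      cumS <- cumsum(wo * yo); cumQ <- cumsum(wo * yo^2)
      S <- cumS[n]; Q <- cumQ[n]
      WL <- cumW[pos]; SL <- cumS[pos]
      WR <- W - WL; SR <- S - SL
      score <- (Q - SL^2 / WL - SR^2 / WR)
    }
    score[!ok] <- Inf
    i <- which.min(score)
    if (score[i] < best$score - 1e-12) {
      best <- list(score = score[i], feature = j,
                   theta = (v[i] + v[i + 1L]) / 2)
    }
  }
  best
}

node_risk <- function(y, w, type) {
  W <- sum(w)
  if (type == "class") {
    p <- sum(w * y) / W
    2 * p * (1 - p) * W
  } else {
    sum(w * y^2) - sum(w * y)^2 / W
  }
}

grow_tree <- function(x, y, w = NULL, type = c("class", "reg"),
                      max_depth = 6L, min_leaf = 5L, mtry = Inf,
                      depth = 0L) {
  type <- match.arg(type)
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  W <- sum(w)
  leaf <- function() {
    if (type == "class") {
      p1 <- sum(w * y) / W
      list(leaf = TRUE, prob = c(1 - p1, p1), n = n, w = W,
           risk = node_risk(y, w, type))
    } else {
      list(leaf = TRUE, value = sum(w * y) / W, n = n, w = W,
           risk = node_risk(y, w, type))
    }
  }
  pure <- if (type == "class") length(unique(y)) < 2L else stats::var(y) < 1e-24
  if (depth >= max_depth || n < 2L * min_leaf || pure) return(leaf())
  sp <- best_split(x, y, w, type, min_leaf, mtry)
  if (!is.finite(sp$score) || sp$score >= node_risk(y, w, type) - 1e-12) {
    return(leaf())
  }
  go_left <- x[, sp$feature] <= sp$theta
  list(leaf = FALSE, feature = sp$feature, theta = sp$theta, beta = Inf,
       n = n, w = W, risk = node_risk(y, w, type),
       left = grow_tree(x[go_left, , drop = FALSE], y[go_left], w[go_left],
                        type, max_depth, min_leaf, mtry, depth + 1L),
       right = grow_tree(x[!go_left, , drop = FALSE], y[!go_left], w[!go_left],
                         type, max_depth, min_leaf, mtry, depth + 1L))
}

#' Sigmoid routing gate of a soft-split tree
#'
#' The probability that a value \code{x} is routed to the LEFT
#' (\eqn{x \le \theta}) child: \eqn{f(x) = 1 / (1 + e^{\beta (x - \theta)})}.
#' As \eqn{\beta \to \infty} the gate recovers the hard CART rule
#' "\eqn{x \le \theta} goes left". The exponent is computed through
#' \code{plogis}, so it cannot overflow.
#'
#' @param x feature value(s).
#' @param theta split threshold.
#' @param beta steepness (> 0); \code{Inf} gives hard routing.
#' @return Left-routing probability in \eqn{[0, 1]}.
#' @examples
#' soft_gate(0, 0, 1)        # 0.5
#' soft_gate(log(3), 0, 1)   # 0.25
#' @export
soft_gate <- function(x, theta, beta) {
  stopifnot(beta > 0)
  if (is.infinite(beta)) return(as.numeric(x <= theta))
  stats::plogis(beta * (theta - x))
}

# Soft prediction: sum over leaves of path-probability x leaf distribution.
predict_tree_soft <- function(node, x) {
  if (node$leaf) return(node$prob[2])
  g <- soft_gate(x[node$feature], node$theta, node$beta)
  g * predict_tree_soft(node$left, x) +
    (1 - g) * predict_tree_soft(node$right, x)
}

predict_tree_soft_matrix <- function(node, x) {
  if (node$leaf) return(rep(node$prob[2], nrow(x)))
  g <- soft_gate(x[, node$feature], node$theta, node$beta)
  g * predict_tree_soft_matrix(node$left, x) +
    (1 - g) * predict_tree_soft_matrix(node$right, x)
}

predict_tree_hard <- function(node, x, what = c("prob", "value")) {
  what <- match.arg(what)
  n <- nrow(x)
  out <- numeric(n)
  rec <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) {
      out[rows] <<- if (what == "prob") node$prob[2] else node$value
      return()
    }
    go_left <- x[rows, node$feature] <= node$theta
    rec(node$left, rows[go_left])
    rec(node$right, rows[!go_left])
  }
  rec(node, seq_len(n))
  out
}

# Assign a finite steepness to every internal node: beta = beta0 / sd of the
# split feature, so the gate width scales with the feature's natural spread.
soften_tree <- function(node, feature_sd, beta0) {
  if (node$leaf) return(node)
  s <- feature_sd[node$feature]
  node$beta <- if (is.finite(beta0)) beta0 / max(s, 1e-8) else Inf
  node$left <- soften_tree(node$left, feature_sd, beta0)
  node$right <- soften_tree(node$right, feature_sd, beta0)
  node
}

n_leaves <- function(node) {
  if (node$leaf) return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

subtree_risk <- function(node) {
  if (node$leaf) return(node$risk)
  subtree_risk(node$left) + subtree_risk(node$right)
}

collapse_to_leaf <- function(node) {
  list(leaf = TRUE, prob = node_prob_of(node), n = node$n, w = node$w,
       risk = node$risk)
}

node_prob_of <- function(node) {
  if (node$leaf) return(node$prob)
  # weighted average of leaf distributions below
  wl <- node$left$w; wr <- node$right$w
  (wl * node_prob_of(node$left) + wr * node_prob_of(node$right)) / (wl + wr)
}

# Weakest-link (cost-complexity) pruning sequence: repeatedly collapse the
# internal node with the smallest per-leaf risk improvement, yielding the
# nested family of subtrees from the full tree down to the root leaf.
prune_sequence <- function(tree) {
  seqs <- list(tree)
  cur <- tree
  while (!cur$leaf) {
    weakest <- function(node, path) {
      if (node$leaf) return(NULL)
      alpha <- (node$risk - subtree_risk(node)) / (n_leaves(node) - 1L)
      cand <- list(alpha = alpha, path = path)
      for (side in c("left", "right")) {
        ch <- weakest(node[[side]], c(path, side))
        if (!is.null(ch) && ch$alpha < cand$alpha) cand <- ch
      }
      cand
    }
    w <- weakest(cur, character(0))
    cur <- prune_at(cur, w$path)
    seqs[[length(seqs) + 1L]] <- cur
  }
  seqs
}

prune_at <- function(node, path) {
  if (!length(path)) return(collapse_to_leaf(node))
  node[[path[1]]] <- prune_at(node[[path[1]]], path[-1])
  node
}

log_loss <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
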