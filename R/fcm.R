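#' Fuzzy c-means clustering
#'
#' Standard FCM alternating optimization: memberships
#' u_ik = 1 / sum_j (||x_k - v_i|| / ||x_k - v_j||)^(2/(m-1)) and centroids
#' v_i = sum_k u_ik^m x_k / sum_k u_ik^m, iterated until the maximum
#' centroid shift falls below `tol` or `max_iter` is reached. A point
#' coinciding with a centroid receives membership 1 for that cluster
#' (shared equally if it coincides with several). Membership rows always
#' sum to 1 and the objective J_m = sum u_ik^m ||x_k - v_i||^2 is
#' non-increasing across iterations.
#'
#' @param points Numeric matrix, one row per point.
#' @param c Number of clusters (default 2: disease-related vs
#'   health-related).
#' @param m Fuzzifier, > 1 (default 2).
#' @param tol Convergence tolerance on the maximum centroid coordinate
#'   shift.
#' @param max_iter Iteration cap; hitting it returns `converged = FALSE`.
#' @param init Optional `c` x `ncol(points)` matrix of initial centroids
#'   (e.g. class-conditional means). When `NULL`, centroids are seeded by a
#'   farthest-point sweep from a random start.
#' @param seed RNG seed used only for the random-start initialization.
#' @return List with `centroids` (`c` x d), `memberships` (n x `c`, rows
#'   summing to 1), `iterations`, `converged`, and `objective` (J_m trace,
#'   one value per iteration).
#' @export
fcm_cluster <- function(points, c = 2, m = 2, tol = 1e-6, max_iter = 100,
                        init = NULL, seed = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  n_distinct <- nrow(unique(points))
  if (n_distinct < c)
    stop("need at least ", c, " distinct points, got ", n_distinct,
         call. = FALSE)
  v <- if (!is.null(init)) {
    stopifnot(nrow(init) == c, ncol(init) == ncol(points))
    as.matrix(init)
  } else {
    fcm_farthest_init(points, c, seed)
  }
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- fcm_memberships(points, v, expo)
  repeat {
    iter <- iter + 1L
    um <- u^m
    v_new <- (t(um) %*% points) / colSums(um)
    # guard: empty cluster (all-zero column) keeps its old centroid
    dead <- colSums(um) == 0
    if (any(dead)) v_new[dead, ] <- v[dead, ]
    u <- fcm_memberships(points, v_new, expo)
    obj <- c(obj, sum((u^m) * sq_dist(points, v_new)))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(centroids = v, memberships = u, iterations = iter,
       converged = converged, objective = obj)
}

# Squared Euclidean distances, n x c.
sq_dist <- function(points, v) {
  d <- matrix(0, nrow(points), nrow(v))
  for (i in seq_len(nrow(v)))
    d[, i] <- colSums((t(points) - v[i, ])^2)
  d
}

# FCM membership matrix for given centroids; handles the zero-distance
# singularity exactly.
fcm_memberships <- function(points, v, expo) {
  d2 <- sq_dist(points, v)
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 <= 0
  any_zero <- rowSums(zero) > 0
  if (any(any_zero))
    u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
  if (any(!any_zero)) {
    dd <- d2[!any_zero, , drop = FALSE]^(expo / 2)  # ||.||^expo
    u[!any_zero, ] <- (1 / dd) / rowSums(1 / dd)
  }
  u
}

# Farthest-point centroid initialization from a seeded random start.
fcm_farthest_init <- function(points, c, seed = NULL) {
  pick <- function() {
    idx <- sample.int(nrow(points), 1)
    for (j in seq_len(c - 1)) {
      d <- apply(sq_dist(points, points[idx, , drop = FALSE]), 1, min)
      idx <- c(idx, which.max(d))
    }
    points[idx, , drop = FALSE]
  }
  if (is.null(seed)) pick() else with_seed(seed, pick())
}

#' Tag FCM clusters as disease- or health-related
#'
#' Given memberships of labeled training points, the cluster carrying the
#' larger total membership mass among diseased points is tagged
#' disease-related and the other health-related. An exact tie is broken
#' deterministically toward the cluster with the higher membership
#' variance. When the disease-mass ratio between the two clusters is below
#' 1.1 the assignment is flagged low-confidence.
#'
#' @param memberships n x 2 membership matrix from [fcm_cluster()].
#' @param diseased Logical vector: `TRUE` for points from diseased
#'   subjects.
#' @return List with `disease` and `health` (column indices), `mass_ratio`,
#'   and `low_confidence`.
#' @export
assign_cluster_roles <- function(memberships, diseased) {
  stopifnot(ncol(memberships) == 2, length(diseased) == nrow(memberships))
  if (all(diseased) || !any(diseased))
    stop("role assignment needs points from both classes", call. = FALSE)
  mass <- colSums(memberships[diseased, , drop = FALSE])
  if (mass[1] == mass[2]) {
    vs <- apply(memberships, 2, stats::var)
    disease <- which.max(vs)
  } else {
    disease <- which.max(mass)
  }
  lo <- min(mass); hi <- max(mass)
  ratio <- if (lo == 0) Inf else hi / lo
  list(disease = disease, health = 3L - disease,
       mass_ratio = ratio, low_confidence = is.finite(ratio) && ratio < 1.1)
}
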