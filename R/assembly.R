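#' @importFrom Matrix sparseMatrix Diagonal t bdiag
NULL

#' Assemble the DG mass matrix
#'
#' Block-diagonal with the exact local P1 mass block `(A/12)*[[2,1,1],[1,2,1],[1,1,2]]`
#' per triangle; symmetric positive definite.
#'
#' @param space a [dg_space()].
#' @param triangles optional triangle subset (used for the bleach matrix).
#' @return sparse `ndof x ndof` matrix.
#' @export
assemble_mass <- function(space, triangles = NULL) {
  nt <- length(space$area)
  ts <- if (is.null(triangles)) seq_len(nt) else triangles
  loc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 12
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (length(ts)) {
    d <- tri_dofs(ts)                 # 3 x |ts|
    ii <- rep(as.vector(d), each = 3L)
    jj <- as.vector(apply(d, 2, function(col) rep(col, 3L)))
    xx <- as.vector(outer(as.vector(loc), space$area[ts]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(space$ndof, space$ndof))
}

#' Assemble a P1-weighted mass matrix
#'
#' Entries `\int w(x) phi_i phi_j dx` with `w` a DG (P1) field, evaluated with
#' the exact cubic formula `\int phi_a phi_b phi_c = 2A a!b!c!/(a+b+c+2)!`.
#' Used for the space-dependent binding rate k_on(x).
#'
#' @param space a [dg_space()].
#' @param w DG coefficient vector (the weight field).
#' @return sparse symmetric matrix.
#' @export
assemble_weighted_mass <- function(space, w) {
  nt <- length(space$area)
  if (length(w) != space$ndof) stop("weight field has wrong length")
  # C[k][i,j] = int phi_k phi_i phi_j / A  (unit-area constants)
  C <- lapply(1:3, function(k) {
    m <- matrix(1 / 60, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      tab <- tabulate(c(k, i, j), 3)
      m[i, j] <- if (any(tab == 3)) 1 / 10 else if (any(tab == 2)) 1 / 30 else 1 / 60
    }
    m
  })
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (t in seq_len(nt)) {
    d <- 3L * (t - 1L) + 1:3
    loc <- space$area[t] * (w[d[1]] * C[[1]] + w[d[2]] * C[[2]] + w[d[3]] * C[[3]])
    ii <- c(ii, rep(d, each = 3L)); jj <- c(jj, rep(d, 3L)); xx <- c(xx, as.vector(loc))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(space$ndof, space$ndof))
}

#' Assemble the bleach matrix
#'
#' `B(u,v) = beta * int_{Omega_B} u v dx` over the bleach-flagged triangles;
#' rows of unflagged triangles are identically zero. Applied to both species.
#'
#' @param space a [dg_space()].
#' @param mesh the underlying [flip_mesh()] (for the bleach flags).
#' @param beta lumped bleach rate (1/s, >= 0).
#' @return sparse matrix.
#' @export
assemble_bleach <- function(space, mesh, beta) {
  if (beta < 0) stop("beta must be >= 0")
  beta * assemble_mass(space, triangles = which(mesh$bleach))
}

# local edge-restriction data: for triangle t and edge (a,b) (vertex ids),
# returns 3x2 matrix of local basis values at the two edge endpoints
edge_trace <- function(mesh, t, a, b) {
  v <- mesh$triangles[t, ]
  cbind(as.numeric(v == a), as.numeric(v == b))
}

# exact integral over an edge of length L of products of linear traces:
# trace given by endpoint values (c0,c1); int = L/6*(2c0d0+c0d1+c1d0+2c1d1)
edge_p1_mass <- function(L) L / 6 * matrix(c(2, 1, 1, 2), 2, 2)

#' Assemble the SIPG diffusion operator
#'
#' The symmetric interior-penalty discretization of `-div(alpha grad u)`:
#' the volume Dirichlet-energy term plus, on interior edges only, the two
#' consistency/symmetry terms and the `sigma/h_e` jump penalty. Membrane and
#' aggregate edges carry no diffusive coupling (those interfaces are handled
#' by the membrane/exchange operators) and the outer boundary is the zero-flux
#' Neumann condition.
#'
#' @param space a [dg_space()].
#' @param edges a [classify_edges()] result.
#' @param alpha diffusion constant (um^2/s, >= 0).
#' @param sigma dimensionless penalty coefficient (> 0); the penalty applied
#'   on an edge is `sigma * alpha / h_e`, so the whole operator scales
#'   linearly with `alpha` and vanishes when diffusion is off.
#' @return sparse symmetric positive semidefinite matrix `D` such that the
#'   weak form contributes `-D %*% u` to du/dt (after mass-matrix inversion).
#' @export
assemble_diffusion_sipg <- function(space, edges, alpha, sigma = 10) {
  if (sigma <= 0) stop("penalty sigma must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  parts <- assemble_diffusion_parts(space, edges)
  alpha * (parts$stiff + sigma * parts$penalty)
}

#' @rdname assemble_diffusion_sipg
#' @return `assemble_diffusion_parts`: list with `stiff` (volume +
#'   consistency terms, to be scaled by `alpha`) and `penalty` (the `1/h_e`
#'   jump penalty, to be scaled by `sigma`). Both symmetric.
#' @export
assemble_diffusion_parts <- function(space, edges) {
  mesh <- space$mesh
  nt <- length(space$area)
  n <- space$ndof
  # volume term: A * grad_i . grad_j
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (t in seq_len(nt)) {
    d <- 3L * (t - 1L) + 1:3
    loc <- space$area[t] * (space$grad[[t]] %*% t(space$grad[[t]]))
    ii <- c(ii, rep(d, each = 3L)); jj <- c(jj, rep(d, 3L)); xx <- c(xx, as.vector(loc))
  }
  int <- which(edges$class == "interior")
  ci <- integer(0); cj <- integer(0); cx <- numeric(0)
  qi <- integer(0); qj <- integer(0); qx <- numeric(0)
  for (e in int) {
    tm <- edges$tri_minus[e]; tp <- edges$tri_plus[e]
    L <- edges$length[e]
    nvec <- c(edges$nx[e], edges$ny[e])
    trm <- edge_trace(mesh, tm, edges$v1[e], edges$v2[e])  # 3x2 endpoint values
    trp <- edge_trace(mesh, tp, edges$v1[e], edges$v2[e])
    dofs <- c(3L * (tm - 1L) + 1:3, 3L * (tp - 1L) + 1:3)
    sgn <- c(rep(1, 3), rep(-1, 3))          # jump = minus - plus (along n-)
    tr6 <- rbind(trm, trp)                   # 6x2 endpoint traces
    gn6 <- c(space$grad[[tm]] %*% nvec, space$grad[[tp]] %*% nvec) / 2  # {grad.n}
    Em <- edge_p1_mass(L)
    # penalty (per unit sigma, h_e = L): sgn_i sgn_j int tr_i tr_j / L
    Ploc <- (sgn %o% sgn) * (tr6 %*% Em %*% t(tr6)) / L
    # consistency/symmetry: -int {grad u . n}[v] - int {grad v . n}[u];
    # constant-gradient times linear trace integrates to L*(c0+c1)/2
    lin <- L * (tr6[, 1] + tr6[, 2]) / 2
    Cu <- -outer(sgn * lin, gn6)             # rows: v dof, cols: u dof
    Cloc <- Cu + t(Cu)
    ci <- c(ci, rep(dofs, 6L)); cj <- c(cj, rep(dofs, each = 6L)); cx <- c(cx, as.vector(Cloc))
    qi <- c(qi, rep(dofs, 6L)); qj <- c(qj, rep(dofs, each = 6L)); qx <- c(qx, as.vector(Ploc))
  }
  stiff <- Matrix::sparseMatrix(i = c(ii, ci), j = c(jj, cj), x = c(xx, cx),
                                dims = c(n, n))
  penalty <- Matrix::sparseMatrix(i = qi, j = qj, x = qx, dims = c(n, n))
  list(stiff = Matrix::drop0((stiff + Matrix::t(stiff)) / 2),
       penalty = Matrix::drop0((penalty + Matrix::t(penalty)) / 2))
}

#' Assemble the free/hindered reaction coupling blocks
#'
#' The first-order hindrance reaction `u <-> u_b`: the u-equation receives
#' `+k_off u_b - k_on(x) u` and the u_b-equation the exact negative, so the
#' pair conserves the total `int (u + u_b) dx`.
#'
#' @param space a [dg_space()].
#' @param k_on_field DG field of binding rates (1/s, >= 0 everywhere).
#' @param k_off scalar release rate (1/s, >= 0).
#' @return list of sparse matrices `Kon` (`int k_on phi_i phi_j`) and
#'   `Koff` (`k_off` times the mass matrix); the stacked right-hand-side
#'   blocks are `[-Kon, +Koff; +Kon, -Koff]`.
#' @export
assemble_local_reaction <- function(space, k_on_field, k_off) {
  if (any(k_on_field < -1e-12)) stop("k_on must be >= 0 everywhere")
  if (k_off < 0) stop("k_off must be >= 0")
  list(Kon = assemble_weighted_mass(space, pmax(k_on_field, 0)),
       Koff = k_off * assemble_mass(space))
}

#' Assemble a directional first-order interface-exchange operator
#'
#' Discretizes a two-sided first-order exchange across an interface edge set
#' (aggregate boundaries or the nuclear membrane in the active-transport
#' model): the cytoplasm side loses `k_fwd * u_cyto` to the enclosed side and
#' receives `k_bwd * u_enclosed`, with the cytoplasm side identified per edge
#' by the indicator stored in the edge table. Edge integrals use the exact P1
#' edge mass matrix `(L/6)[[2,1],[1,2]]`. Each edge integrand is multiplied
#' by `scale` (um), which converts the per-area rates (1/s) into edge fluxes;
#' testing with the constant-1 function on both sides gives exactly zero
#' (mass conservation).
#'
#' @param space a [dg_space()].
#' @param edges a [classify_edges()] result.
#' @param class which edge class to integrate over (`"aggregate"` or
#'   `"membrane"`).
#' @param k_fwd rate cytoplasm -> enclosed region (1/s, >= 0).
#' @param k_bwd rate enclosed region -> cytoplasm (1/s, >= 0).
#' @param scale per-edge length factor (um); default 1 gives the bare edge
#'   integral. [interface_scale_factors()] provides the region-area /
#'   region-perimeter factors used by the transport model.
#' @return sparse matrix `X` contributing `+X %*% u` to the u equation.
#' @export
assemble_directional_exchange <- function(space, edges, class, k_fwd, k_bwd,
                                          scale = 1) {
  if (k_fwd < 0 || k_bwd < 0) stop("exchange rates must be >= 0")
  sel <- which(edges$class == class)
  scale <- rep_len(scale, length(sel))
  mesh <- space$mesh
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (q in seq_along(sel)) {
    e <- sel[q]
    tc <- edges$tri_minus[e]   # cytoplasm side by construction
    ta <- edges$tri_plus[e]
    if (mesh$compartment[tc] != "cytoplasm")
      stop("interface edge without a cytoplasm side")
    trc <- edge_trace(mesh, tc, edges$v1[e], edges$v2[e])
    tra <- edge_trace(mesh, ta, edges$v1[e], edges$v2[e])
    Em <- scale[q] * edge_p1_mass(edges$length[e])
    dc <- 3L * (tc - 1L) + 1:3; da <- 3L * (ta - 1L) + 1:3
    Ecc <- trc %*% Em %*% t(trc); Eca <- trc %*% Em %*% t(tra)
    Eac <- tra %*% Em %*% t(trc); Eaa <- tra %*% Em %*% t(tra)
    add <- function(rows, cols, m) {
      ii <<- c(ii, rep(rows, 3L)); jj <<- c(jj, rep(cols, each = 3L))
      xx <<- c(xx, as.vector(m))
    }
    add(da, dc, k_fwd * Eac)    # enclosed side gains k_fwd u_C
    add(da, da, -k_bwd * Eaa)   # enclosed side loses k_bwd u_A
    add(dc, dc, -k_fwd * Ecc)   # cytoplasm loses k_fwd u_C
    add(dc, da, k_bwd * Eca)    # cytoplasm gains k_bwd u_A
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(space$ndof, space$ndof))
}

#' Assemble the semipermeable-membrane operator
#'
#' `M(u,v) = -p int_{Gamma_M} [[u]] . [[v]] ds`: diffusive flux across the
#' nuclear membrane proportional to the concentration jump, permeability `p`
#' in um/s. Negative semidefinite; vanishes on fields continuous across the
#' membrane.
#'
#' @param space a [dg_space()].
#' @param edges a [classify_edges()] result.
#' @param p membrane permeability (um/s, >= 0).
#' @return sparse matrix contributing `+M %*% u` to the u equation.
#' @export
assemble_permeable_membrane <- function(space, edges, p) {
  if (p < 0) stop("permeability p must be >= 0")
  mesh <- space$mesh
  sel <- which(edges$class == "membrane")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (e in sel) {
    tm <- edges$tri_minus[e]; tp <- edges$tri_plus[e]
    trm <- edge_trace(mesh, tm, edges$v1[e], edges$v2[e])
    trp <- edge_trace(mesh, tp, edges$v1[e], edges$v2[e])
    dofs <- c(3L * (tm - 1L) + 1:3, 3L * (tp - 1L) + 1:3)
    sgn <- c(rep(1, 3), rep(-1, 3))
    tr6 <- rbind(trm, trp)
    Em <- edge_p1_mass(edges$length[e])
    loc <- -p * (sgn %o% sgn) * (tr6 %*% Em %*% t(tr6))
    ii <- c(ii, rep(dofs, 3L + 3L)); jj <- c(jj, rep(dofs, each = 6L))
    xx <- c(xx, as.vector(loc))
  }
  if (!length(ii))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(space$ndof, space$ndof)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(space$ndof, space$ndof))
}

#' Interface scale factors for the exchange operators
#'
#' Converts the first-order per-intensity rates (1/s) of the compartment
#' exchange models into edge-flux integrands: every edge of an interface
#' carries the factor (enclosed region area) / (interface perimeter), so that
#' the summed flux over the interface reproduces the lumped two-compartment
#' exchange of the enclosed region exactly (for a well-mixed region) and the
#' fitted rates are independent of the mesh resolution. The same factor
#' multiplies gain and loss terms, so exact mass conservation is preserved.
#'
#' @param mesh a [flip_mesh()].
#' @param edges a [classify_edges()] result.
#' @param class `"aggregate"` (per-aggregate area over its boundary length)
#'   or `"membrane"` (nucleus area over membrane length).
#' @return numeric vector, one factor (um) per edge of that class, in the
#'   order the edges appear in `edges`.
#' @export
interface_scale_factors <- function(mesh, edges, class) {
  ra <- region_areas(mesh)
  per <- interface_perimeters(edges)
  sel <- which(edges$class == class)
  if (class == "membrane") {
    rep(ra$nucleus / per$membrane, length(sel))
  } else if (class == "aggregate") {
    ids <- as.character(edges$aggregate_id[sel])
    unname(ra$aggregate[ids] / per$aggregate[ids])
  } else stop("class must be 'membrane' or 'aggregate'")
}
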