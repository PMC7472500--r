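# A synthetic neutral right-foot marker set (mm; lab X anterior, Y up,
# Z right-lateral) with all measured landmarks, for living-body-style tests.
neutral_foot_markers <- function() {
  list(
    P1 = c(220, 28, -25),
    H1 = c(170, 30, -25), H2 = c(170, 32, 0), H5 = c(170, 28, 25),
    B1 = c(80, 35, -28), B2 = c(82, 36, -5), B5 = c(78, 30, 30),
    NV = c(75, 40, -30), ST = c(60, 25, -33), PT = c(55, 20, 33),
    C1 = c(5, 45, 0), C2 = c(2, 8, 0),
    LM = c(60, 70, 30), MM = c(60, 70, -30),
    TT = c(40, 350, 0), HF = c(45, 330, 40)
  )
}

# replicate a static marker layout into an n-frame trajectory_set,
# optionally applying one rigid motion (R, t) per frame
make_traj <- function(markers, n = 1, rate = 100, R = NULL, t = NULL) {
  series <- lapply(markers, function(p) {
    m <- matrix(p, n, 3, byrow = TRUE)
    if (!is.null(R)) {
      for (i in seq_len(n)) {
        Ri <- if (is.list(R)) R[[i]] else R
        ti <- if (is.list(t)) t[[i]] else if (is.null(t)) c(0, 0, 0) else t
        m[i, ] <- as.vector(Ri %*% p) + ti
      }
    }
    m
  })
  trajectory_set(series, rate)
}
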