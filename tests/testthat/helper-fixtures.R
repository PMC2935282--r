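## Shared fixtures, built in code. Small cells keep the suite fast while
## exercising every code path (triclinic geometry, symmetry images,
## water-like surface atoms).

orthoCell <- function() unitCell(16, 17, 18)

tricCell <- function() unitCell(12, 13, 14, 90, 100, 90)

## 3-atom triclinic model matching the frozen external-oracle values
oracleModel <- function() {
  crystalModel(tricCell(),
               data.frame(element = c("C", "N", "O"),
                          x = c(1.0, 4.5, 2.2), y = c(2.0, 5.5, 8.1),
                          z = c(3.0, 2.5, 6.3),
                          occ = c(1, 0.8, 1), b = c(10, 15, 20)))
}

smallSpec <- function(seed = 3, ...) {
  toySpec(nAtoms = 8, cell = c(16, 17, 18), dmin = 2.5, seed = seed, ...)
}

## brute-force periodic minimum-image distances from one point to a matrix
bruteDist <- function(cell, x, pts) {
  fx <- fractionalize(cell, x)
  fp <- fractionalize(cell, pts)
  d <- fp - matrix(fx, nrow(pts), 3, byrow = TRUE)
  d <- d - round(d)
  sqrt(rowSums((d %*% t(cell@orthMat))^2))
}
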