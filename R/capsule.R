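## Spherocylinder ("capsule") geometry shared by the image renderer and the
## model-based axis fitter. The 2D projection of a spherocylinder of length L
## and width W is a capsule: a (L - W) x W rectangle capped by two half-discs
## of diameter W. Edges are rendered with a Gaussian edge-spread profile in
## the signed distance to the capsule boundary; defocus widens that profile.

## signed distance (um) from points (x, y) to the boundary of a capsule
## centred at (cx, cy) with orientation theta, half-length a = (L - W)/2 and
## radius r = W/2; negative inside
capsuleSignedDistance <- function(x, y, cx, cy, theta, a, r) {
  xr <-  cos(theta) * (x - cx) + sin(theta) * (y - cy)
  yr <- -sin(theta) * (x - cx) + cos(theta) * (y - cy)
  dx <- pmax(abs(xr) - a, 0)
  sqrt(dx * dx + yr * yr) - r
}

## analytic projected area of the capsule, um^2: W*(L - W) + pi*(W/2)^2
capsuleArea <- function(L, W) W * (L - W) + pi * (W / 2)^2

## edge-spread coverage profile: 1 deep inside, 0 far outside, with a
## Gaussian transition of width sigma (um) across the boundary
capsuleProfile <- function(d, sigma) stats::pnorm(-d / sigma)
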