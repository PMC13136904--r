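#ifndef G4DIMER_GEOM_H
#define G4DIMER_GEOM_H

#include <cmath>

// Minimal 3-vector algebra for the hard-cylinder model.
struct V3 {
  double x, y, z;
};

inline V3 v3(double x, double y, double z) { V3 r = {x, y, z}; return r; }
inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator-(V3 a) { return v3(-a.x, -a.y, -a.z); }
inline V3 operator*(double s, V3 a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(V3 a) { return dot(a, a); }
inline double norm(V3 a) { return std::sqrt(norm2(a)); }

// Solid finite cylinder: center c, unit axis u, radius R, half-height h.
struct Cyl {
  V3 c, u;
  double R, h;
};

// Support point of a solid cylinder in direction d (d need not be unit).
inline V3 support_cyl(const Cyl &C, V3 d) {
  double du = dot(d, C.u);
  V3 p = C.c + ((du >= 0.0) ? C.h : -C.h) * C.u;
  V3 dr = d - du * C.u;
  // re-orthogonalize: for d nearly parallel to the axis, fp noise would
  // otherwise give dr a spurious axial part that R/|dr| amplifies into a
  // support point far outside the body
  dr = dr - dot(dr, C.u) * C.u;
  double n = norm(dr);
  if (n > 1e-9 * (std::fabs(du) + n)) p = p + (C.R / n) * dr;
  return p;
}

// ---- closest point on simplex features (origin as query point) ----

// Closest point to origin on segment ab; bary[] gets the supporting vertices.
inline V3 closest_seg(V3 a, V3 b, int keep[2], int ia, int ib, int &nkeep) {
  V3 ab = b - a;
  double denom = dot(ab, ab);
  double t = (denom > 0.0) ? -dot(a, ab) / denom : 0.0;
  if (t <= 0.0) { nkeep = 1; keep[0] = ia; return a; }
  if (t >= 1.0) { nkeep = 1; keep[0] = ib; return b; }
  nkeep = 2; keep[0] = ia; keep[1] = ib;
  return a + t * ab;
}

// Closest point to origin on triangle abc (Ericson, RTCD 5.1.5).
inline V3 closest_tri(V3 a, V3 b, V3 c, int keep[3], int ia, int ib, int ic,
                      int &nkeep) {
  V3 ab = b - a, ac = c - a, ap = -a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { nkeep = 1; keep[0] = ia; return a; }

  V3 bp = -b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { nkeep = 1; keep[0] = ib; return b; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    nkeep = 2; keep[0] = ia; keep[1] = ib;
    return a + v * ab;
  }

  V3 cp = -c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { nkeep = 1; keep[0] = ic; return c; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    nkeep = 2; keep[0] = ia; keep[1] = ic;
    return a + w * ac;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    nkeep = 2; keep[0] = ib; keep[1] = ic;
    return b + w * (c - b);
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  nkeep = 3; keep[0] = ia; keep[1] = ib; keep[2] = ic;
  return a + v * ab + w * ac;
}

// Is origin outside the plane of (a,b,c) on the opposite side from d?
inline int origin_outside_face(V3 a, V3 b, V3 c, V3 d) {
  V3 n = cross(b - a, c - a);
  double signd = dot(n, d - a);
  double signo = dot(n, -a);
  // treat degenerate faces as "not outside"
  if (std::fabs(signd) < 1e-18) return 0;
  return (signd * signo < 0.0) ? 1 : 0;
}

// Closest point to origin on/in tetrahedron; returns v and reduced simplex.
// Sets inside=1 when the origin is contained.
inline V3 closest_tetra(V3 *s, int keep[4], int &nkeep, int &inside) {
  inside = 0;
  int out0, out1, out2, out3;
  double vol6 = dot(cross(s[1] - s[0], s[2] - s[0]), s[3] - s[0]);
  if (std::fabs(vol6) < 1e-18) {
    // degenerate (coplanar) tetrahedron: fall back to scanning all faces
    out0 = out1 = out2 = out3 = 1;
  } else {
    out0 = origin_outside_face(s[1], s[2], s[3], s[0]);
    out1 = origin_outside_face(s[0], s[2], s[3], s[1]);
    out2 = origin_outside_face(s[0], s[1], s[3], s[2]);
    out3 = origin_outside_face(s[0], s[1], s[2], s[3]);
  }
  if (!out0 && !out1 && !out2 && !out3) {
    inside = 1; nkeep = 4;
    keep[0] = 0; keep[1] = 1; keep[2] = 2; keep[3] = 3;
    return v3(0, 0, 0);
  }
  double best = 1e300;
  V3 bestv = v3(0, 0, 0);
  int bkeep[3], bn = 0;
  int tk[3], tn;
  if (out0) {
    V3 v = closest_tri(s[1], s[2], s[3], tk, 1, 2, 3, tn);
    double d2 = norm2(v);
    if (d2 < best) { best = d2; bestv = v; bn = tn; for (int i = 0; i < tn; ++i) bkeep[i] = tk[i]; }
  }
  if (out1) {
    V3 v = closest_tri(s[0], s[2], s[3], tk, 0, 2, 3, tn);
    double d2 = norm2(v);
    if (d2 < best) { best = d2; bestv = v; bn = tn; for (int i = 0; i < tn; ++i) bkeep[i] = tk[i]; }
  }
  if (out2) {
    V3 v = closest_tri(s[0], s[1], s[3], tk, 0, 1, 3, tn);
    double d2 = norm2(v);
    if (d2 < best) { best = d2; bestv = v; bn = tn; for (int i = 0; i < tn; ++i) bkeep[i] = tk[i]; }
  }
  if (out3) {
    V3 v = closest_tri(s[0], s[1], s[2], tk, 0, 1, 2, tn);
    double d2 = norm2(v);
    if (d2 < best) { best = d2; bestv = v; bn = tn; for (int i = 0; i < tn; ++i) bkeep[i] = tk[i]; }
  }
  nkeep = bn;
  for (int i = 0; i < bn; ++i) keep[i] = bkeep[i];
  return bestv;
}

// GJK intersection test between two solid cylinders (closest-point variant).
// Touching configurations (distance ~ 0 but no interior overlap) are below
// the resolution of the tolerance and may report either way; they form a
// measure-zero set under the sampling used here.
inline bool cyl_overlap(const Cyl &A, const Cyl &B) {
  const double eps_inside = 1e-12;   // |v|^2 below this => overlap
  const double tol_sep = 1e-10;      // separation margin
  V3 d0 = A.c - B.c;
  if (norm2(d0) < 1e-20) return true;  // concentric => certainly overlapping
  // cheap bounding-sphere reject
  double ra = std::sqrt(A.R * A.R + A.h * A.h);
  double rb = std::sqrt(B.R * B.R + B.h * B.h);
  if (norm(d0) > ra + rb) return false;

  V3 s[4];
  int n = 0;
  V3 v = support_cyl(A, d0) - support_cyl(B, -d0);
  s[n++] = v;
  for (int iter = 0; iter < 200; ++iter) {
    double vlen2 = norm2(v);
    if (vlen2 < eps_inside) return true;
    double vlen = std::sqrt(vlen2);
    V3 d = -v;  // search direction toward origin
    V3 a = support_cyl(A, d) - support_cyl(B, -d);
    // upper bound on how far MD extends toward the origin along d-hat:
    double proj = dot(a, d) / vlen;  // support extent toward the origin
    if (proj < tol_sep) return false;  // support plane separates the origin
    // delta = |v|^2 - dot(v, a) -> 0 as the closest point converges while
    // the origin stays outside; for interior origins delta stays > |v|^2.
    double delta = vlen2 + proj * vlen;
    if (delta <= 1e-10 * (vlen2 > 1.0 ? vlen2 : 1.0)) return false;
    // add new point, reduce simplex to closest feature
    s[n++] = a;
    int keep[4], nkeep = 0, inside = 0;
    V3 nv;
    if (n == 2) {
      nv = closest_seg(s[0], s[1], keep, 0, 1, nkeep);
    } else if (n == 3) {
      nv = closest_tri(s[0], s[1], s[2], keep, 0, 1, 2, nkeep);
    } else {
      nv = closest_tetra(s, keep, nkeep, inside);
      if (inside) return true;
    }
    // compact simplex
    V3 tmp[4];
    for (int i = 0; i < nkeep; ++i) tmp[i] = s[keep[i]];
    for (int i = 0; i < nkeep; ++i) s[i] = tmp[i];
    n = nkeep;
    if (norm2(nv) >= vlen2 * (1.0 - 1e-14)) {
      // no strict decrease: converged at positive distance
      return norm2(nv) < eps_inside;
    }
    v = nv;
  }
  // slow convergence happens only near the boundary; classify as no overlap
  return false;
}

// ---- dimer energetics ----
// State row layout (18 doubles per dimer):
//   0:2  center A, 3:5 axis A (unit), 6:8 rim direction A (unit, perp to axis)
//   9:11 center B, 12:14 axis B,      15:17 rim direction B
// Cylinder A carries its linker patch on its +axis base, B on its -axis base;
// the stacking pair is (A +base center, B -base center).

struct DimerE {
  double energy;   // in u0 units: -1, 0
  bool feasible;   // false if overlap or linker well violated
  bool stacked;
};

inline DimerE dimer_energy_row(const double *r, double R, double H,
                               double R0, double R1) {
  double h = H / 2.0;
  V3 ca = v3(r[0], r[1], r[2]), ua = v3(r[3], r[4], r[5]), wa = v3(r[6], r[7], r[8]);
  V3 cb = v3(r[9], r[10], r[11]), ub = v3(r[12], r[13], r[14]), wb = v3(r[15], r[16], r[17]);
  DimerE out;
  out.energy = 0.0; out.feasible = true; out.stacked = false;
  V3 linkA = ca + h * ua + R * wa;
  V3 linkB = cb - h * ub + R * wb;
  if (norm2(linkA - linkB) > 4.0 * R0 * R0) { out.feasible = false; return out; }
  Cyl A = {ca, ua, R, h}, B = {cb, ub, R, h};
  if (cyl_overlap(A, B)) { out.feasible = false; return out; }
  V3 stackA = ca + h * ua;
  V3 stackB = cb - h * ub;
  if (norm2(stackA - stackB) <= 4.0 * R1 * R1) { out.energy = -1.0; out.stacked = true; }
  return out;
}

#endif
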