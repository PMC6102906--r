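name: A
bounds:
- -0.2
- 5.8
- -6.3
- 4.2
obstacles:
- x:
  - -0.1
  - 0.0
  - 0.0
  - -0.1
  'y':
  - -0.1
  - -0.1
  - 4.1
  - 4.1
- x:
  - -0.1
  - 5.7
  - 5.7
  - -0.1
  'y':
  - 4.0
  - 4.0
  - 4.1
  - 4.1
- x:
  - -0.1
  - 4.1
  - 4.1
  - -0.1
  'y':
  - -0.1
  - -0.1
  - 0.0
  - 0.0
- x:
  - 4.0
  - 4.1
  - 4.1
  - 4.0
  'y':
  - -0.1
  - -0.1
  - 1.0
  - 1.0
- x:
  - 4.0
  - 4.1
  - 4.1
  - 4.0
  'y':
  - 1.8
  - 1.8
  - 4.1
  - 4.1
- x:
  - 4.0
  - 4.1
  - 4.1
  - 4.0
  'y':
  - -6.1
  - -6.1
  - -0.1
  - -0.1
- x:
  - 5.6
  - 5.7
  - 5.7
  - 5.6
  'y':
  - -6.1
  - -6.1
  - 4.1
  - 4.1
- x:
  - 4.0
  - 5.7
  - 5.7
  - 4.0
  'y':
  - -6.2
  - -6.2
  - -6.1
  - -6.1
doorways:
  x: 4.05
  'y': 1.4
  width: 0.8
  normal_theta: 0.0
objects:
- id: 1
  class: desk
  x: 2.0
  'y': 3.7
  theta: -1.5707963
  width: 1.2
  depth: 0.6
  height: 0.75
  z_base: 0.0
  shape: box
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: yes
- id: 2
  class: bottle
  x: 2.05
  'y': 3.5
  theta: 0.0
  width: 0.06
  depth: 0.06
  height: 0.25
  z_base: 0.75
  shape: cylinder
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: no
- id: 3
  class: opened_door
  x: 4.05
  'y': 1.4
  theta: 0.0
  width: 0.8
  depth: 0.1
  height: 2.0
  z_base: 0.0
  shape: door
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: no
- id: 4
  class: person
  x: 4.85
  'y': -1.5
  theta: 0.0
  width: 0.5
  depth: 0.5
  height: 1.7
  z_base: 0.0
  shape: cylinder
  vx: 0.0
  vy: 0.0
  dynamic: yes
  solid: yes
start_pose:
- 2.0
- 1.8
- 1.5707963
tasks:
- step: 1
  mode: auto
  action: goto
  target_class: desk
- step: 2
  mode: auto
  action: pick
  target_class: bottle
- step: 3
  mode: none
  action: drink
- step: 4
  mode: command
  action: move
  command: backward
  amount: 1.0
- step: 5
  mode: command
  action: rotate
  command: rotate_right
  amount: 1.5707963
  target_heading: 0.0
- step: 6
  mode: auto
  action: pass_door
  target_class: opened_door
- step: 7
  mode: command
  action: rotate
  command: rotate_right
  amount: 1.5707963
  target_heading: -1.5707963
- step: 8
  mode: auto
  action: goto
  target_class: person
- step: 9
  mode: none
  action: converse
walk_to:
- 4.85
- -5.0
walk_speed: 0.5
walk_trigger: 2.5
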